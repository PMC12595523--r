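roster <- load_roster()

test_that("packaged hermaphrodite roster partitions 302 cells into classes", {
  expect_equal(nrow(roster$cells), 302)
  expect_equal(anyDuplicated(roster$cells$cell_name), 0)
  sizes <- lengths(roster$class_index)
  expect_equal(sum(sizes), 302)
  all_members <- unlist(roster$class_index, use.names = FALSE)
  expect_equal(anyDuplicated(all_members), 0)      # classes are disjoint
  expect_identical(roster$class_index[["AVK"]], c("AVKL", "AVKR"))
  expect_identical(roster$class_index[["VA"]], paste0("VA", 1:12))
  expect_true(all(sizes >= 1 & sizes <= 13))
})

test_that("expand_class is total: exact, state-suffix, cell-level, unknown", {
  expect_identical(expand_class(roster, "AVK"),
                   list(label = "AVK", cells = c("AVKL", "AVKR"), status = "exact"))
  on <- expand_class(roster, "AWC_ON")
  expect_identical(on$cells, c("AWCL", "AWCR"))
  expect_identical(on$status, "state_ambiguous")
  expect_identical(expand_class(roster, "awc_off")$cells, c("AWCL", "AWCR"))
  asel <- expand_class(roster, "ASEL")
  expect_identical(asel$cells, "ASEL")
  expect_identical(asel$status, "cell_level")
  miss <- expand_class(roster, "NOT_A_NEURON")
  expect_identical(miss$cells, character())
  expect_identical(miss$status, "unknown")
  expect_identical(expand_class(roster, "")$status, "unknown")
})

test_that("expansion of distinct fixture CSV columns gives disjoint cell sets", {
  fx <- nested_fixture()
  tab <- load_expression_csv(fx$csv_path)
  sets <- lapply(tab$class_names, function(cl) expand_class(roster, cl)$cells)
  all_cells <- unlist(sets)
  expect_equal(anyDuplicated(all_cells), 0)
})

test_that("load_model binds named meshes to roster cells, rest become context", {
  fx <- nested_fixture()
  model <- load_model(fx$obj_path, roster)
  expect_s3_class(model, "anatomy_model")
  expect_setequal(names(model$neuron_meshes), fx$cells$cell_name)
  expect_identical(names(model$context_meshes), "body")

  # soma centroid oracle: vertex average of the generated sphere = center
  for (cell in c("AVKL", "RICR")) {
    expected <- unlist(fx$cells[fx$cells$cell_name == cell, c("x", "y", "z")])
    centroid <- colMeans(model$neuron_meshes[[cell]]$vertices)
    expect_equal(unname(soma_position(model, cell)), unname(expected),
                 tolerance = 1e-6)
    expect_equal(unname(centroid), unname(expected), tolerance = 1e-6)
  }
  # every soma inside its mesh bounding box
  for (cell in names(model$neuron_meshes)) {
    bb <- wormsight:::mesh_bbox(model$neuron_meshes[[cell]])
    sp <- soma_position(model, cell)
    expect_true(all(sp >= bb["min", ] - 1e-9 & sp <= bb["max", ] + 1e-9))
  }
})

test_that("mesh-name matching is case-insensitive and honors a strip regex", {
  dir <- withr::local_tempdir()
  objs <- list(
    avkl = wormsight:::scene_object("avkl", sphere_mesh(c(1, 2, 3), 1)),
    pref = wormsight:::scene_object("WBneuron.AVKR", sphere_mesh(c(1, 2, -3), 1)))
  write_obj(objs, file.path(dir, "m.obj"))
  model <- load_model(file.path(dir, "m.obj"), roster, name_pattern = "^WBneuron\\.")
  expect_setequal(names(model$neuron_meshes), c("AVKL", "AVKR"))

  bad <- list(x = wormsight:::scene_object("blob", sphere_mesh(c(0, 0, 0), 1)))
  write_obj(bad, file.path(dir, "bad.obj"))
  expect_error(load_model(file.path(dir, "bad.obj"), roster), "no mesh name")
})

test_that("model load then re-export preserves mesh names and vertex counts", {
  fx <- nested_fixture()
  objs <- read_obj(fx$obj_path)
  out <- file.path(fx$dir, "reexport.obj")
  write_obj(objs, out)
  objs2 <- read_obj(out)
  expect_identical(names(objs2), names(objs))
  for (nm in names(objs)) {
    expect_equal(nrow(objs2[[nm]]$mesh$vertices), nrow(objs[[nm]]$mesh$vertices))
    expect_equal(objs2[[nm]]$mesh$faces, objs[[nm]]$mesh$faces)
  }
})
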