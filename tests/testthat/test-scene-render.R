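roster <- load_roster()

scene_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fx <- nested_fixture(dir)
  tab <- load_expression_csv(fx$csv_path)
  part <- partition_by_signature(compute_signatures(tab, c("g1", "g2", "g3"), roster))
  cm <- assign_colors(part, explicit = list("100" = "green", "110" = "blue",
                                            "111" = "orange"))
  model <- load_model(fx$obj_path, roster)
  list(fx = fx, part = part, cm = cm, model = model,
       scene = build_scene(model, cm, part))
}

distinct_pixel_hex <- function(img) {
  px <- matrix(img, ncol = 3)
  unique(grDevices::rgb(px[, 1], px[, 2], px[, 3]))
}

test_that("build_scene assigns block, neutral and context materials", {
  sf <- scene_fixture()
  sc <- sf$scene
  expect_setequal(sc$neuron_names, sf$fx$cells$cell_name)
  expect_identical(sc$context_names, "body")
  expect_equal(sc$objects[["AVKL"]]$color, c(0, 1, 0, 1))       # g1-only block
  expect_equal(sc$objects[["RIML"]]$color, c(0, 0, 1, 1))
  expect_equal(sc$objects[["body"]]$color[4], sf$cm$context_color[4])

  empty <- build_scene(sf$model)     # no partition: all neutral + context
  expect_length(empty$cell_colors, 0)
  expect_equal(empty$objects[["AVKL"]]$color, wormsight:::as_rgba("grey85"))
})

test_that("cells without meshes get soma-sphere stand-ins at their positions", {
  sf <- scene_fixture()
  part2 <- sf$part
  part2$blocks[["100"]] <- c(part2$blocks[["100"]], "PVT")  # roster cell, no mesh
  pos <- matrix(c(42, 1, 2), 1, dimnames = list("PVT", NULL))
  sc <- build_scene(sf$model, sf$cm, part2, fallback_positions = pos)
  expect_true("PVT" %in% names(sc$objects))
  expect_equal(unname(colMeans(sc$objects[["PVT"]]$mesh$vertices)),
               c(42, 1, 2), tolerance = 1e-6)
  # colored cell unknown everywhere is an error
  part3 <- sf$part
  part3$blocks[["100"]] <- c(part3$blocks[["100"]], "XXQQ")
  expect_error(build_scene(sf$model, sf$cm, part3), "XXQQ")
})

test_that("flat render emits only material colors at the requested resolution", {
  sf <- scene_fixture()
  spec <- camera_spec(preset = "whole_worm", model = sf$model,
                      width = 200, height = 150)
  img <- render_scene(sf$scene, spec, background = "white")
  expect_equal(dim(img), c(150, 200, 3))
  ctx <- sf$cm$context_color
  blended <- wormsight:::quantize8((1 - ctx[4]) * c(1, 1, 1) + ctx[4] * ctx[1:3])
  allowed <- c("#FFFFFF",                                     # background
               grDevices::rgb(blended[1], blended[2], blended[3]),
               "#00FF00", "#0000FF", "#FFA500")               # block colors
  seen <- distinct_pixel_hex(img)
  expect_true(all(seen %in% allowed))
  expect_true(all(c("#00FF00", "#0000FF", "#FFA500") %in% seen))  # all blocks visible
})

test_that("a green cube filling the view renders all-green", {
  cube <- wormsight:::new_mesh(
    rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)) * 50,
    rbind(c(1, 2, 3), c(1, 3, 4)))
  obj <- list(CUBE = wormsight:::scene_object("CUBE", cube, c(0, 1, 0, 1)))
  sc <- structure(list(objects = obj, neuron_names = "CUBE",
                       context_names = character(), cell_colors = obj["CUBE"]),
                  class = "scene")
  spec <- camera_spec(eye = c(0, 0, -10), target = c(0, 0, 0),
                      width = 64, height = 64, fov = 40)
  img <- render_scene(sc, spec, background = "black")
  expect_identical(distinct_pixel_hex(img), "#00FF00")
})

test_that("renders and turntable frames are deterministic, frame 0 = start camera", {
  sf <- scene_fixture()
  spec <- camera_spec(preset = "head", model = sf$model, width = 120, height = 90)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_scene(sf$scene, spec, p1)
  render_scene(sf$scene, spec, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)), readBin(p2, raw(), file.size(p2)))

  dir <- withr::local_tempdir()
  paths <- render_turntable(sf$scene, spec, 4, dir)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  expect_identical(readBin(paths[1], raw(), file.size(paths[1])),
                   readBin(p1, raw(), file.size(p1)))
})

test_that("scene export round-trips the cell-to-color binding in every format", {
  sf <- scene_fixture()
  want <- lapply(sf$scene$objects, `[[`, "color")
  dir <- withr::local_tempdir()

  export_scene(sf$scene, file.path(dir, "s.gltf"), "gltf")
  got <- lapply(read_gltf(file.path(dir, "s.gltf")), `[[`, "color")
  expect_identical(got[names(want)], want)

  export_scene(sf$scene, file.path(dir, "s.obj"), "obj")
  got <- lapply(read_obj(file.path(dir, "s.obj")), `[[`, "color")
  expect_identical(got[names(want)], want)

  export_scene(sf$scene, file.path(dir, "ply"), "ply")
  files <- list.files(file.path(dir, "ply"), full.names = TRUE)
  got <- lapply(do.call(c, lapply(files, read_ply)), `[[`, "color")
  expect_identical(got[names(want)], want)
})
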