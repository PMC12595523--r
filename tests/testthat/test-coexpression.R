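roster <- load_roster()

nested_tab <- local({
  fx <- nested_fixture(withr::local_tempdir(.local_envir = teardown_env()))
  load_expression_csv(fx$csv_path)
})

test_that("signatures follow class membership over the query genes", {
  sigs <- compute_signatures(nested_tab, c("g1", "g2", "g3"), roster)
  expect_length(sigs, 302)
  expect_equal(unname(sigs[["RICL"]]), c(TRUE, TRUE, TRUE))   # class in all three
  expect_equal(unname(sigs[["AVKR"]]), c(TRUE, FALSE, FALSE)) # g1 only
  expect_equal(unname(sigs[["AVAL"]]), c(FALSE, FALSE, FALSE))# expresses none
  expect_error(compute_signatures(nested_tab, character(), roster), "at least one")
  expect_error(compute_signatures(nested_tab, "nope", roster),
               class = "wormsight_unknown_gene")
})

test_that("nested design partitions into exactly the three inclusion blocks", {
  sigs <- compute_signatures(nested_tab, c("g1", "g2", "g3"), roster)
  part <- partition_by_signature(sigs)
  expect_setequal(names(part$blocks), c("100", "110", "111"))
  expect_identical(part$blocks[["100"]], c("AVKL", "AVKR"))
  expect_identical(part$blocks[["110"]], c("RIML", "RIMR"))
  expect_identical(part$blocks[["111"]], c("RICL", "RICR"))
  expect_equal(length(part$background), 302 - 6)
  expect_length(intersect(unlist(part$blocks), part$background), 0)
})

test_that("partition matches the exhaustive 2^G enumeration oracle", {
  for (seed in 1:10) {
    n_cls <- sample(3:10, 1)
    g <- sample(1:5, 1)
    spec <- fixture_spec(n_classes = n_cls, n_genes = g, sparsity = 0.4, seed = seed)
    dir <- withr::local_tempdir()
    expr <- make_synthetic_expression(spec, file.path(dir, "e.csv"))
    tab <- load_expression_csv(expr$csv_path)
    part <- partition_by_signature(
      compute_signatures(tab, names(expr$design), roster))
    expect_same_partition(part, oracle_partition(expr$design, roster))
  }
})

test_that("adding a query gene only refines the partition", {
  for (seed in 11:15) {
    spec <- fixture_spec(n_classes = 8, n_genes = 4, sparsity = 0.5, seed = seed)
    dir <- withr::local_tempdir()
    expr <- make_synthetic_expression(spec, file.path(dir, "e.csv"))
    tab <- load_expression_csv(expr$csv_path)
    genes <- names(expr$design)
    for (g in 2:length(genes)) {
      coarse <- partition_by_signature(
        compute_signatures(tab, genes[seq_len(g - 1)], roster))
      fine <- partition_by_signature(compute_signatures(tab, genes[seq_len(g)], roster))
      fine_blocks <- c(fine$blocks, list(background = fine$background))
      for (blk in coarse$blocks) {
        # every coarse block is a union of fine blocks
        parts <- Filter(function(fb) length(intersect(fb, blk)) > 0, fine_blocks)
        expect_setequal(unlist(parts), blk)
      }
    }
  }
})

test_that("color assignment is deterministic, ordered by co-expression depth", {
  sigs <- compute_signatures(nested_tab, c("g1", "g2", "g3"), roster)
  part <- partition_by_signature(sigs)
  cm1 <- assign_colors(part, seed = 42L)
  cm2 <- assign_colors(part, seed = 42L)
  expect_identical(serialize(cm1, NULL), serialize(cm2, NULL))
  # popcount-then-binary ordering: single-positive first, triple last
  expect_identical(names(cm1$entries), c("100", "110", "111"))
  # injective palette -> bijection blocks -> colors
  hex <- vapply(cm1$entries, wormsight:::color_to_hex, "")
  expect_equal(anyDuplicated(hex), 0)
})

test_that("explicit color maps win and must cover every block", {
  part <- partition_by_signature(
    compute_signatures(nested_tab, c("g1", "g2", "g3"), roster))
  cm <- assign_colors(part, explicit = list("100" = "green", "110" = "blue",
                                            "111" = "orange"))
  expect_equal(cm$entries[["100"]], c(0, 1, 0, 1))
  expect_equal(cm$entries[["110"]], c(0, 0, 1, 1))
  expect_equal(wormsight:::color_to_hex(cm$entries[["111"]]), "#FFA500")
  expect_error(assign_colors(part, explicit = list("100" = "green")), "111")
})

test_that("sender/receiver overlay equals the two-gene signature partition", {
  fx <- make_fig1c_fixture(withr::local_tempdir())
  tab <- load_expression_csv(fx$csv_path)
  roles <- signaling_overlay(tab, fx$ligand_gene, fx$receptor_gene, roster)
  expect_identical(sort(names(roles)[roles == "sender"]), c("AVKL", "AVKR"))
  expect_equal(sum(roles == "receiver"), 2 * length(fx$receptor_classes))
  expect_equal(sum(roles == "both"), 0)

  sigs <- compute_signatures(tab, c(fx$ligand_gene, fx$receptor_gene), roster)
  part <- partition_by_signature(sigs)
  expect_identical(sort(names(roles)[roles == "sender"]), part$blocks[["10"]])
  expect_identical(sort(names(roles)[roles == "receiver"]), part$blocks[["01"]])
  expect_identical(sort(names(roles)[roles == "none"]), part$background)

  # self-pair: every expressing cell is "both"
  both <- signaling_overlay(tab, fx$ligand_gene, fx$ligand_gene, roster)
  expect_setequal(names(both)[both == "both"], c("AVKL", "AVKR"))
  expect_true(all(both[setdiff(names(both), c("AVKL", "AVKR"))] == "none"))
})

test_that("partition export carries class, signature, color and role columns", {
  part <- partition_by_signature(
    compute_signatures(nested_tab, c("g1", "g2", "g3"), roster))
  cm <- assign_colors(part)
  df <- partition_to_csv(part, cm, roster)
  expect_equal(nrow(df), 302)
  expect_named(df, c("cell_name", "class_name", "signature_bits", "color_hex", "role"))
  expect_identical(df$signature_bits[df$cell_name == "RICL"], "111")
  expect_identical(df$class_name[df$cell_name == "AVKL"], "AVK")
})
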