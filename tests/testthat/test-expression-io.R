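roster <- load_roster()

test_that("expression CSV loads, validates, and round-trips bit-for-bit", {
  csv <- withr::local_tempfile(fileext = ".csv")
  vals <- matrix(c(5, 0, 2, 0,
                   0, 3, 1, 0,
                   0, 0, 0, 7), nrow = 3, byrow = TRUE)
  write_tiny_csv(csv, c("g1", "g2", "g3"), c("AVK", "RIM", "RIC", "AVA"), vals)
  tab <- load_expression_csv(csv, threshold_label = "synthetic")
  expect_identical(tab$gene_ids, c("g1", "g2", "g3"))
  expect_identical(tab$class_names, c("AVK", "RIM", "RIC", "AVA"))
  expect_equal(unname(tab$values), vals)
  expect_length(tab$flagged_classes, 0)

  out <- withr::local_tempfile(fileext = ".csv")
  write_expression_csv(tab, out)
  tab2 <- load_expression_csv(out)
  expect_identical(tab2$gene_ids, tab$gene_ids)
  expect_identical(tab2$class_names, tab$class_names)
  expect_identical(tab2$values, tab$values)
})

test_that("orientation auto-detect is involution-safe on transposed tables", {
  csv <- withr::local_tempfile(fileext = ".csv")
  vals <- matrix(c(5, 0, 2, 0, 0, 3, 1, 0), nrow = 2, byrow = TRUE)
  write_tiny_csv(csv, c("unc-1", "unc-2"), c("AVK", "RIM", "RIC", "AVA"), vals)
  tab <- load_expression_csv(csv)

  tcsv <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(tcsv, c("AVK", "RIM", "RIC", "AVA"), c("unc-1", "unc-2"), t(vals))
  ttab <- load_expression_csv(tcsv)
  expect_identical(ttab$gene_ids, tab$gene_ids)
  expect_identical(ttab$class_names, tab$class_names)
  expect_identical(ttab$values, tab$values)
})

test_that("unknown columns are flagged, vocabulary misses are errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(csv, "g1", c("AVK", "Intestine"), matrix(c(1, 2), 1))
  tab <- load_expression_csv(csv)
  expect_identical(tab$flagged_classes, "Intestine")

  bad <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(bad, "g1", c("foo", "bar"), matrix(c(1, 2), 1))
  expect_error(load_expression_csv(bad), "neuron class")
  expect_error(load_expression_csv(withr::local_tempfile()), "not found")
})

test_that("missing cells read as 0 and duplicate gene ids are rejected", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,AVK,RIM", "g1,5,", "g2,,3"), csv)
  expect_message(tab <- load_expression_csv(csv), "missing")
  expect_equal(unname(tab$values), matrix(c(5, 0, 0, 3), 2, byrow = TRUE))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,AVK,RIM", "Flp-1,5,0", "flp-1,0,3"), dup)
  expect_error(load_expression_csv(dup), "duplicate gene")
})

test_that("gene lookup is case-insensitive with edit-distance suggestions", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(csv, c("flp-1", "flp-2"), c("AVK", "RIM"),
                 matrix(c(5, 0, 0, 3), 2, byrow = TRUE))
  tab <- load_expression_csv(csv)
  expect_identical(lookup_gene(tab, "FLP-1"), "flp-1")

  # Levenshtein oracle: adist("flp1", c("flp-1","flp-2")) = c(1, 2)
  expect_equal(as.vector(utils::adist("flp1", c("flp-1", "flp-2"))), c(1, 2))
  err <- tryCatch(lookup_gene(tab, "flp1"), wormsight_unknown_gene = identity)
  expect_s3_class(err, "wormsight_unknown_gene")
  expect_identical(err$suggestions, c("flp-1", "flp-2"))

  err2 <- tryCatch(lookup_gene(tab, ""), wormsight_unknown_gene = identity)
  expect_length(err2$suggestions, 0)
})

test_that("expressing_classes uses a strict cutoff and is monotone in min_value", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(csv, c("g1", "gz"), c("AVK", "RIM", "RIC", "AVA"),
                 matrix(c(5, 0, 2, 0,
                          0, 0, 0, 0), 2, byrow = TRUE))
  tab <- load_expression_csv(csv)
  expect_setequal(expressing_classes(tab, "g1"), c("AVK", "RIC"))
  expect_identical(expressing_classes(tab, "g1", min_value = 4), "AVK")
  expect_identical(expressing_classes(tab, "g1", min_value = 5), character())
  expect_identical(expressing_classes(tab, "gz"), character())

  cuts <- sort(stats::runif(10, 0, 6))
  sizes <- vapply(cuts, function(m) length(expressing_classes(tab, "g1", m)), 0L)
  expect_true(all(diff(sizes) <= 0))
})
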