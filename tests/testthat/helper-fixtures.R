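# Shared fixture builders and independent oracles.

# write a tiny expression CSV by hand (independent of the generators)
write_tiny_csv <- function(path, genes, classes, values) {
  lines <- paste0("gene,", paste(classes, collapse = ","))
  for (i in seq_along(genes)) {
    lines <- c(lines, paste(c(genes[i], values[i, ]), collapse = ","))
  }
  writeLines(lines, path)
  path
}

# nested three-gene fixture on disk: g1 in {AVK,RIM,RIC}, g2 in {RIM,RIC},
# g3 in {RIC}
nested_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  spec <- fixture_spec(design = nested_design())
  model <- make_synthetic_model(spec, dir)
  expr <- make_synthetic_expression(spec, file.path(dir, "expression.csv"))
  c(model, expr, list(spec = spec, dir = dir))
}

# Independent partition oracle: enumerate all 2^G candidate signatures
# and collect, for each, the cells whose class-membership pattern over
# the design matches it exactly. Works straight from the gene ->
# class-set design, bypassing expression tables and signature grouping.
oracle_partition <- function(design, roster, cells = roster$cells$cell_name) {
  genes <- names(design)
  G <- length(genes)
  cls <- class_of_cell(roster, cells)
  M <- matrix(vapply(genes, function(g) cls %in% design[[g]],
                     logical(length(cells))), ncol = G)
  blocks <- list()
  background <- character()
  for (code in 0:(2^G - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(G)])  # bit i = gene i
    members <- cells[colSums(abs(t(M) - bits)) == 0]
    key <- paste(bits, collapse = "")
    if (code == 0) background <- sort(members)
    else if (length(members)) blocks[[key]] <- sort(members)
  }
  list(blocks = blocks, background = background)
}

expect_same_partition <- function(part, oracle) {
  expect_setequal(as.character(names(part$blocks)),
                  as.character(names(oracle$blocks)))
  for (k in names(oracle$blocks)) expect_identical(part$blocks[[k]], oracle$blocks[[k]])
  expect_identical(part$background, oracle$background)
}

# random gene -> class-set design over the fixture's classes
random_design <- function(classes, n_genes, seed) {
  set.seed(seed)
  design <- lapply(seq_len(n_genes), function(i) {
    classes[stats::runif(length(classes)) < stats::runif(1, 0.2, 0.8)]
  })
  names(design) <- paste0("g", seq_len(n_genes))
  design
}
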