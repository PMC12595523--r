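#' Synthetic worm fixtures
#'
#' Generators for a toy worm model (named soma spheres on a translucent
#' body tube) and CeNGEN-style expression CSVs with known structure, so
#' the whole pipeline is testable without downloading the real
#' single-cell matrices or the Virtual Worm. Class names reuse real
#' C. elegans neuron classes (AVK, RIM, RIC, AVA, ...) so the
#' nomenclature code paths are exercised on the true vocabulary. All
#' generators are fully deterministic under `seed`: the same spec gives
#' byte-identical output files. The generators emulate the *structure*
#' of the real inputs (named per-neuron geometry, class-resolved
#' thresholded expression), not CeNGEN's count distributions or real
#' neuron morphology.
#'
#' @name fixtures
#' @keywords internal
NULL

# fixed pools of real class names so fixtures stay deterministic
paired_class_pool <- function() {
  c("AVK", "RIM", "RIC", "AVA", "AVB", "ASH", "AWC", "ASE", "AIY", "RIA",
    "AVD", "AVE", "AWA", "AWB", "ASI", "ASJ", "ASK", "ADL", "AFD", "BAG")
}
single_class_pool <- function() {
  c("ALA", "AVG", "AVL", "AVM", "RID", "RIH", "RIS", "DVA", "DVB", "DVC")
}

#' Specify a synthetic fixture
#'
#' @param n_classes Number of neuron classes (>= 1).
#' @param cells_per_class 1 (singleton classes) or 2 (left/right pairs).
#' @param n_genes Number of genes (ignored when `design` is given).
#' @param design Optional named list, gene -> character vector of
#'   expressing classes. When `NULL`, a random design is drawn:
#'   Bernoulli(`sparsity`) per gene x class under `seed`.
#' @param sparsity Probability a (gene, class) pair is expressing in a
#'   random design.
#' @param body_length Body tube length in model units.
#' @param soma_radius Soma sphere radius in model units.
#' @param neurite Whether to add a thin neurite tube per neuron.
#' @param seed Integer seed controlling every random draw.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_classes = 3, cells_per_class = 2, n_genes = 3,
                         design = NULL, sparsity = 0.3,
                         body_length = 100, soma_radius = 2,
                         neurite = FALSE, seed = 1L) {
  stopifnot(n_classes >= 1, cells_per_class %in% c(1, 2), n_genes >= 1,
            sparsity >= 0, sparsity <= 1, body_length > 0, soma_radius > 0)
  pool <- if (cells_per_class == 2) paired_class_pool() else single_class_pool()
  if (n_classes > length(pool)) {
    stop("at most ", length(pool), " classes with cells_per_class=",
         cells_per_class, call. = FALSE)
  }
  classes <- pool[seq_len(n_classes)]
  if (!is.null(design)) {
    unknown <- setdiff(unique(unlist(design)), classes)
    if (length(unknown)) {
      stop("design references classes outside the fixture: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    n_genes <- length(design)
    if (is.null(names(design))) names(design) <- paste0("g", seq_along(design))
  }
  structure(
    list(n_classes = n_classes, cells_per_class = cells_per_class,
         classes = classes, n_genes = n_genes, design = design,
         sparsity = sparsity, body_length = body_length,
         soma_radius = soma_radius, neurite = neurite, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_cells <- function(spec) {
  if (spec$cells_per_class == 2) {
    data.frame(
      cell_name = as.vector(rbind(paste0(spec$classes, "L"), paste0(spec$classes, "R"))),
      class_name = rep(spec$classes, each = 2), stringsAsFactors = FALSE)
  } else {
    data.frame(cell_name = spec$classes, class_name = spec$classes,
               stringsAsFactors = FALSE)
  }
}

#' Generate a toy worm model
#'
#' Soma spheres are placed at deterministic positions along the body
#' axis (x); left/right pair members mirror each other in z, so their
#' soma positions are equal up to the sign of the left-right
#' coordinate. A translucent body tube along x is the single context
#' mesh. Mesh object names are exactly the cell names.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if absent).
#' @return List with `obj_path`, `roster_path`, `cells` (data.frame
#'   with positions) invisibly usable for oracles.
#' @export
make_synthetic_model <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- fixture_cells(spec)
  n_cls <- spec$n_classes
  xs <- spec$body_length * seq_len(n_cls) / (n_cls + 1)
  lr_off <- 4 * spec$soma_radius
  pos <- matrix(0, nrow(cells), 3, dimnames = list(cells$cell_name, c("x", "y", "z")))
  for (i in seq_len(n_cls)) {
    if (spec$cells_per_class == 2) {
      pos[2 * i - 1, ] <- c(xs[i], 0,  lr_off)   # L
      pos[2 * i, ]     <- c(xs[i], 0, -lr_off)   # R
    } else {
      pos[i, ] <- c(xs[i], 0, 0)
    }
  }
  objects <- list()
  objects[["body"]] <- scene_object(
    "body", tube_mesh(c(0, 0, 0), c(spec$body_length, 0, 0),
                      radius = 8 * spec$soma_radius, n_seg = 16, n_len = 10),
    c(0.5, 0.5, 0.5, 1), opacity = 0.15)
  for (cell in cells$cell_name) {
    m <- sphere_mesh(pos[cell, ], spec$soma_radius)
    if (spec$neurite) {
      tip <- pos[cell, ] + c(min(10 * spec$soma_radius, spec$body_length / 4), 0, 0)
      tube <- tube_mesh(pos[cell, ], tip, radius = spec$soma_radius / 4, n_seg = 6, n_len = 2)
      m <- new_mesh(rbind(m$vertices, tube$vertices),
                    rbind(m$faces, tube$faces + nrow(m$vertices)))
    }
    objects[[cell]] <- scene_object(cell, m, c(0.8, 0.8, 0.8, 1))
  }
  obj_path <- file.path(dir, "model.obj")
  write_obj(objects, obj_path)
  roster_path <- file.path(dir, "roster.csv")
  utils::write.csv(cells, roster_path, row.names = FALSE, quote = FALSE)
  cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  list(obj_path = obj_path, roster_path = roster_path, cells = cells)
}

#' Generate a CeNGEN-style expression CSV
#'
#' Genes as rows, one column per class. An explicit design is
#' reproduced exactly (expressed cells get value 5, a comfortably
#' positive level); a random design draws Bernoulli(`sparsity`)
#' expression per (gene, class) under the spec seed, with expressed
#' values uniform in (1, 10) rounded to 3 decimals for byte-stable
#' files.
#'
#' @param spec A `fixture_spec`.
#' @param path Output CSV path.
#' @return List with `csv_path`, `design` (the realized gene -> class
#'   map) and `values` (the matrix written).
#' @export
make_synthetic_expression <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  classes <- spec$classes
  if (!is.null(spec$design)) {
    genes <- names(spec$design)
    vals <- matrix(0, length(genes), length(classes),
                   dimnames = list(genes, classes))
    for (g in genes) vals[g, spec$design[[g]]] <- 5
    design <- spec$design
  } else {
    genes <- paste0("g", seq_len(spec$n_genes))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(spec$seed)
    on <- matrix(stats::runif(length(genes) * length(classes)) < spec$sparsity,
                 length(genes), length(classes))
    mag <- matrix(round(stats::runif(length(genes) * length(classes), 1, 10), 3),
                  length(genes), length(classes))
    vals <- ifelse(on, mag, 0)
    dimnames(vals) <- list(genes, classes)
    design <- lapply(seq_along(genes), function(i) classes[on[i, ]])
    names(design) <- genes
  }
  df <- data.frame(gene = genes, vals, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  list(csv_path = path, design = design, values = vals)
}

#' Nested three-gene co-expression design
#'
#' The inclusion-chain design behind monoamine-style co-expression
#' figures: gene 1 in classes \{1,2,3\}, gene 2 in \{2,3\}, gene 3 in
#' \{3\}, giving exactly three non-empty signature blocks
#' (g1-only, g1+g2, g1+g2+g3).
#'
#' @param spec A `fixture_spec` with `n_classes >= 3`.
#' @return A named design list usable as `fixture_spec(design = ...)`.
#' @export
nested_design <- function(spec = fixture_spec()) {
  stopifnot(spec$n_classes >= 3)
  cl <- spec$classes
  list(g1 = cl[1:3], g2 = cl[2:3], g3 = cl[3])
}

#' Ligand/receptor broadcasting fixture
#'
#' Emulates a neuropeptide broadcasting network: one ligand gene
#' (`flp-1`) confined to the two-cell AVK-like class, one receptor gene
#' (`frpr-7`) expressed in at least half of all classes but not in the
#' ligand class, so the overlay has exactly two sender cells, no
#' "both" cells, and 2 x (number of receptor classes) receivers.
#'
#' @param dir Output directory.
#' @param n_classes Total classes (>= 4).
#' @return List with `obj_path`, `roster_path`, `csv_path`,
#'   `ligand_gene`, `receptor_gene`, `ligand_classes`,
#'   `receptor_classes`, `spec`.
#' @export
make_fig1c_fixture <- function(dir = tempfile("fig1c_"), n_classes = 12) {
  stopifnot(n_classes >= 4)
  spec0 <- fixture_spec(n_classes = n_classes, cells_per_class = 2, seed = 7L)
  classes <- spec0$classes
  ligand_classes <- classes[1]                       # AVK
  n_rec <- max(ceiling(n_classes / 2), 2)
  receptor_classes <- setdiff(classes, ligand_classes)[seq_len(n_rec)]
  design <- list("flp-1" = ligand_classes, "frpr-7" = receptor_classes)
  spec <- fixture_spec(n_classes = n_classes, cells_per_class = 2,
                       design = design, seed = 7L)
  model <- make_synthetic_model(spec, dir)
  expr <- make_synthetic_expression(spec, file.path(dir, "expression.csv"))
  list(obj_path = model$obj_path, roster_path = model$roster_path,
       csv_path = expr$csv_path, ligand_gene = "flp-1", receptor_gene = "frpr-7",
       ligand_classes = ligand_classes, receptor_classes = receptor_classes,
       spec = spec)
}
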