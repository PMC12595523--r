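#' Canonical neuron roster
#'
#' The adult hermaphrodite nervous system has exactly 302 neurons, each
#' belonging to one anatomical/transcriptomic class (AVK has two cells
#' AVKL and AVKR; VA has twelve, VA1..VA12; and so on). Single-cell
#' RNA-seq matrices report expression per class, while 3D models carry
#' one mesh per individual neuron; the roster is the bridge. The
#' packaged roster is a frozen two-column CSV (`cell_name,class_name`)
#' under `inst/extdata/neuron_roster.csv`.
#'
#' @name neuron_roster
#' @keywords internal
NULL

#' Load a neuron roster
#'
#' @param path Path to a two-column CSV with columns
#'   `cell_name,class_name`. Defaults to the packaged hermaphrodite
#'   roster (302 cells, 118 classes).
#' @return A `neuron_roster`: list with `cells` (data.frame with
#'   `cell_name`, `class_name`), `class_index` (named list, class ->
#'   ordered cell names) and `class_index_names`.
#' @export
#' @examples
#' r <- load_roster()
#' nrow(r$cells)              # 302
#' expand_class(r, "AVK")$cells
load_roster <- function(path = system.file("extdata", "neuron_roster.csv",
                                           package = "wormsight")) {
  if (!nzchar(path) || !file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_name", "class_name") %in% colnames(df))) {
    stop("roster must have columns cell_name,class_name", call. = FALSE)
  }
  df$cell_name <- trimws(df$cell_name)
  df$class_name <- trimws(df$class_name)
  if (anyDuplicated(df$cell_name)) {
    stop("duplicate cell names in roster: ",
         paste(unique(df$cell_name[duplicated(df$cell_name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$class_name))) stop("empty class_name in roster", call. = FALSE)
  idx <- split(df$cell_name, df$class_name)
  idx <- lapply(idx, natural_sort)   # VA2 before VA10
  structure(
    list(cells = df, class_index = idx, class_index_names = names(idx)),
    class = "neuron_roster"
  )
}

#' @export
print.neuron_roster <- function(x, ...) {
  cat(sprintf("<neuron_roster> %d cells in %d classes\n",
              nrow(x$cells), length(x$class_index)))
  invisible(x)
}

#' Expand a class label to its member cells
#'
#' Total function: it never throws. An exact class label returns its
#' members; labels with a state suffix (e.g. `"AWC_ON"`, `"AWC_OFF"` --
#' CeNGEN distinguishes functional states the anatomy cannot) fall back
#' to the base class's cells with `status = "state_ambiguous"`; a label
#' that is itself a cell name (e.g. `"ASEL"`) returns that single cell;
#' anything else returns an empty set with `status = "unknown"`.
#'
#' @param roster A `neuron_roster`.
#' @param label Class label from an expression-table column.
#' @return List with `cells` (character), `status` (one of `"exact"`,
#'   `"state_ambiguous"`, `"cell_level"`, `"unknown"`), `label`.
#' @export
expand_class <- function(roster, label) {
  stopifnot(inherits(roster, "neuron_roster"))
  lab <- trimws(as.character(label)[1])
  res <- function(cells, status) list(label = lab, cells = cells, status = status)
  if (!nzchar(lab)) return(res(character(), "unknown"))
  up <- toupper(lab)
  classes_up <- toupper(roster$class_index_names)
  i <- match(up, classes_up)
  if (!is.na(i)) return(res(roster$class_index[[i]], "exact"))
  j <- match(up, toupper(roster$cells$cell_name))
  if (!is.na(j)) return(res(roster$cells$cell_name[j], "cell_level"))
  base <- sub("_[A-Za-z0-9]+$", "", up)
  k <- match(base, classes_up)
  if (!is.na(k)) return(res(roster$class_index[[k]], "state_ambiguous"))
  res(character(), "unknown")
}

natural_sort <- function(x) {
  stem <- sub("[0-9]+$", "", x)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", x)))
  num[!grepl("[0-9]+$", x)] <- 0L
  x[order(stem, num, x)]
}

#' Class of a cell
#' @param roster A `neuron_roster`.
#' @param cell_names Character vector of cell names.
#' @return Character vector of class names (`NA` for unknown cells).
#' @export
class_of_cell <- function(roster, cell_names) {
  roster$cells$class_name[match(toupper(cell_names), toupper(roster$cells$cell_name))]
}
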