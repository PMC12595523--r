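#' Gene-by-neuron-class expression tables
#'
#' An `expression_table` holds a genes x neuron-class matrix of
#' non-negative expression values, as distributed by the CeNGEN
#' consortium (thresholded single-cell RNA-seq matrices, one column per
#' transcriptomic neuron class). Values in those matrices have already
#' passed a detection threshold, so "expressed" defaults to "strictly
#' positive"; `min_value` is available for continuous tables.
#'
#' @name expression_table
#' @keywords internal
NULL

new_expression_table <- function(values, threshold_label = "unknown",
                                 flagged_classes = character()) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(
    list(
      gene_ids = rownames(values),
      class_names = colnames(values),
      values = values,
      threshold_label = threshold_label,
      flagged_classes = flagged_classes
    ),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "<expression_table> %d genes x %d classes (%s)\n",
    length(x$gene_ids), length(x$class_names), x$threshold_label
  ))
  if (length(x$flagged_classes)) {
    cat("  flagged (non-class) columns:",
        paste(utils::head(x$flagged_classes, 8), collapse = ", "),
        if (length(x$flagged_classes) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

validate_expression_table <- function(tab) {
  g <- tab$gene_ids
  if (anyDuplicated(tolower(g))) {
    dup <- unique(tolower(g)[duplicated(tolower(g))])
    stop("duplicate gene identifiers after case-folding: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$class_names)) {
    stop("duplicate class column names", call. = FALSE)
  }
  if (any(!is.finite(tab$values)) || any(tab$values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  invisible(tab)
}

# Count header tokens matching a class vocabulary.  A token matches if,
# after trimming, it equals a class name or an individual cell name
# (CeNGEN uses e.g. ASEL/ASER and AWC_ON/AWC_OFF as column labels), or
# is a known class after stripping a state suffix ("AWC_ON" -> "AWC").
match_class_vocab <- function(tokens, roster) {
  vocab <- c(roster$class_index_names, roster$cells$cell_name)
  tok <- trimws(tokens)
  base <- sub("_[A-Za-z0-9]+$", "", tok)
  toupper(tok) %in% toupper(vocab) | toupper(base) %in% toupper(roster$class_index_names)
}

#' Load a CeNGEN-style expression CSV
#'
#' Reads a comma-separated gene x neuron-class matrix. The first row and
#' first column are headers; remaining cells are non-negative expression
#' values (empty cells are read as 0, reported once per file via a
#' message). Orientation is detected by counting header tokens that
#' match the roster's class/cell vocabulary on each axis; the axis with
#' more matches becomes the class axis. Columns that match no known
#' class are retained but flagged (CeNGEN exports can carry
#' non-neuronal cell types).
#'
#' @param path Path to a CSV file.
#' @param orientation One of `"auto"`, `"genes_as_rows"`,
#'   `"genes_as_cols"`.
#' @param roster A neuron roster (defaults to the packaged
#'   hermaphrodite roster) providing the class vocabulary.
#' @param threshold_label Free-text provenance tag stored on the table
#'   (e.g. `"threshold 2"`, `"threshold 4"`, `"synthetic"`).
#' @return An `expression_table`.
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("gene,AVK,RIM", "flp-1,5,0", "cat-1,0,3"), csv)
#' tab <- load_expression_csv(csv)
#' expressing_classes(tab, "flp-1")
load_expression_csv <- function(path, orientation = c("auto", "genes_as_rows", "genes_as_cols"),
                                roster = load_roster(),
                                threshold_label = basename(path)) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("unreadable CSV '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(raw) < 2 || nrow(raw) < 1) stop("CSV too small to be an expression matrix", call. = FALSE)

  row_ids <- as.character(raw[[1]])
  col_ids <- colnames(raw)[-1]
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(as.character(col)), numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(row_ids, col_ids))
  if (anyNA(num)) {
    message("load_expression_csv: ", sum(is.na(num)),
            " missing cell(s) read as 0 in '", basename(path), "'")
    num[is.na(num)] <- 0
  }

  col_match <- sum(match_class_vocab(col_ids, roster))
  row_match <- sum(match_class_vocab(row_ids, roster))
  if (orientation == "auto") {
    if (col_match == 0 && row_match == 0) {
      stop("no row or column header matches any known neuron class; ",
           "this does not look like a neuron-class expression table", call. = FALSE)
    }
    orientation <- if (col_match >= row_match) "genes_as_rows" else "genes_as_cols"
  }
  if (orientation == "genes_as_cols") num <- t(num)
  if (sum(match_class_vocab(colnames(num), roster)) == 0) {
    stop("no header on the class axis matches any known neuron class", call. = FALSE)
  }
  flagged <- colnames(num)[!match_class_vocab(colnames(num), roster)]
  tab <- new_expression_table(num, threshold_label = threshold_label,
                              flagged_classes = flagged)
  validate_expression_table(tab)
}

#' Write an expression table back to CSV
#'
#' Emits the same RFC-4180 dialect `load_expression_csv()` reads: genes
#' as rows, first column `gene`, one column per class. A load/write/load
#' cycle reproduces gene ids, class names and values exactly.
#'
#' @param table An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene = table$gene_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve a gene query against a table
#'
#' Case-insensitive exact match on the gene symbol. A miss raises an
#' error of class `wormsight_unknown_gene` carrying up to five nearest
#' symbols by Levenshtein edit distance in its `suggestions` field.
#'
#' @param table An `expression_table`.
#' @param query Gene symbol, e.g. `"flp-1"` (any case).
#' @return The canonical gene id as stored in the table.
#' @export
lookup_gene <- function(table, query) {
  stopifnot(inherits(table, "expression_table"))
  if (!is.character(query) || length(query) != 1 || is.na(query) || !nzchar(trimws(query))) {
    stop(unknown_gene_error("", character()))
  }
  q <- trimws(query)
  hit <- which(tolower(table$gene_ids) == tolower(q))
  if (length(hit) == 1) return(table$gene_ids[hit])
  d <- utils::adist(tolower(q), tolower(table$gene_ids))[1, ]
  sug <- table$gene_ids[order(d, table$gene_ids)]
  sug <- utils::head(sug[sort(d) <= max(3, nchar(q))], 5)
  stop(unknown_gene_error(q, sug))
}

unknown_gene_error <- function(query, suggestions) {
  msg <- if (!nzchar(query)) {
    "empty gene query"
  } else if (length(suggestions)) {
    paste0("gene '", query, "' not found; did you mean: ",
           paste(suggestions, collapse = ", "), "?")
  } else {
    paste0("gene '", query, "' not found")
  }
  structure(
    class = c("wormsight_unknown_gene", "error", "condition"),
    list(message = msg, call = NULL, query = query, suggestions = suggestions)
  )
}

#' Classes expressing a gene
#'
#' Returns the neuron-class labels whose value for `gene` is strictly
#' greater than `min_value`. With the default `min_value = 0` any
#' nonzero entry of an already-thresholded CeNGEN-style matrix counts
#' as expressed.
#'
#' @param table An `expression_table`.
#' @param gene Gene symbol (resolved with [lookup_gene()]).
#' @param min_value Strict lower cutoff on the expression value.
#' @return Character vector of class names (possibly empty).
#' @export
expressing_classes <- function(table, gene, min_value = 0) {
  stopifnot(is.numeric(min_value), length(min_value) == 1, min_value >= 0)
  id <- lookup_gene(table, gene)
  v <- table$values[id, ]
  table$class_names[v > min_value]
}
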