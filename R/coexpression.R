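#' Co-expression signatures and partitions
#'
#' The core computation: given an ordered query gene list, every neuron
#' gets an *expression signature* — a bit vector recording which of the
#' query genes its transcriptomic class expresses. Grouping neurons by
#' exact signature yields a disjoint partition: with query
#' `(cat-1, tdc-1, tbh-1)` the cat-1-only block, the cat-1+tdc-1 block
#' and the triple-positive block are exactly the green/blue/orange
#' groups of a monoaminergic co-expression figure. Neurons expressing
#' none of the query genes form the background. A ligand/receptor
#' sender-receiver overlay is the two-gene special case with the four
#' signatures renamed to roles.
#'
#' @name coexpression
#' @keywords internal
NULL

signature_key <- function(bits) paste(as.integer(bits), collapse = "")

#' Compute per-cell expression signatures
#'
#' Bit `i` of a cell's signature is `TRUE` iff the cell's class is in
#' `expressing_classes(table, genes[i], min_value)`. Cells whose class
#' does not appear in the table (or appears only under an unknown
#' label) get the all-false signature.
#'
#' @param table An `expression_table`.
#' @param genes Ordered character vector of query genes (resolved with
#'   [lookup_gene()]; at least one).
#' @param roster A `neuron_roster`.
#' @param min_value Strict expression cutoff (see
#'   [expressing_classes()]); applied uniformly to all query genes.
#' @return Named list, cell name -> logical vector (named by canonical
#'   gene ids) over all roster cells.
#' @export
compute_signatures <- function(table, genes, roster = load_roster(), min_value = 0) {
  if (length(genes) < 1) stop("need at least one query gene", call. = FALSE)
  genes <- vapply(genes, function(g) lookup_gene(table, g), "")
  if (anyDuplicated(genes)) stop("duplicate query genes", call. = FALSE)

  # per gene: the set of cells whose class expresses it
  gene_cells <- lapply(genes, function(g) {
    cls <- expressing_classes(table, g, min_value)
    unique(unlist(lapply(cls, function(cl) expand_class(roster, cl)$cells)))
  })

  cells <- roster$cells$cell_name
  bits <- vapply(gene_cells, function(set) cells %in% set, logical(length(cells)))
  bits <- matrix(bits, nrow = length(cells), dimnames = list(cells, unname(genes)))
  sigs <- lapply(seq_along(cells), function(i) {
    stats::setNames(bits[i, ], unname(genes))   # keep names when |genes| = 1
  })
  names(sigs) <- cells
  sigs
}

#' Partition cells by exact signature
#'
#' @param signatures Output of [compute_signatures()].
#' @return A `signature_partition`: list with `query_genes`, `blocks`
#'   (named list, signature key such as `"110"` -> sorted cell names;
#'   the all-false key never appears) and `background` (cells
#'   expressing no query gene).
#' @export
partition_by_signature <- function(signatures) {
  if (!length(signatures)) {
    return(structure(list(query_genes = character(), blocks = list(),
                          background = character()),
                     class = "signature_partition"))
  }
  genes <- names(signatures[[1]])
  keys <- vapply(signatures, signature_key, "")
  zero <- strrep("0", length(genes))
  background <- sort(names(signatures)[keys == zero])
  grouped <- split(names(signatures), keys)
  grouped <- grouped[names(grouped) != zero]
  blocks <- lapply(grouped, sort)
  structure(
    list(query_genes = genes, blocks = blocks, background = background),
    class = "signature_partition"
  )
}

#' @export
print.signature_partition <- function(x, ...) {
  cat(sprintf("<signature_partition> %d gene(s): %s\n",
              length(x$query_genes), paste(x$query_genes, collapse = ", ")))
  for (k in names(x$blocks)) {
    on <- x$query_genes[strsplit(k, "")[[1]] == "1"]
    cat(sprintf("  [%s] {%s}: %d cells\n", k, paste(on, collapse = "+"),
                length(x$blocks[[k]])))
  }
  cat(sprintf("  background: %d cells\n", length(x$background)))
  invisible(x)
}

# Blocks ordered by (popcount, then signature read as a binary number
# with gene 1 as the most significant bit), so deeper co-expression
# gets later palette colors.
order_blocks <- function(keys) {
  pc <- vapply(keys, function(k) sum(strsplit(k, "")[[1]] == "1"), 0)
  val <- vapply(keys, function(k) strtoi(k, base = 2), 0)
  keys[order(pc, val)]
}

default_palette <- function(n) {
  # Okabe-Ito first (colorblind-safe), then evenly spaced HCL hues
  base <- grDevices::palette.colors(min(n, 8), palette = "Okabe-Ito")
  if (n > 8) base <- c(base, grDevices::hcl.colors(n - 8, "Dark 3"))
  unname(base[seq_len(n)])
}

as_rgba <- function(col) {
  if (is.numeric(col)) return(quantize8(col))
  quantize8(as.vector(grDevices::col2rgb(col, alpha = TRUE)) / 255)
}

#' Assign colors to partition blocks
#'
#' An explicit map (named by signature key, or a list of
#' `gene-subset = color`) always wins and must cover every block.
#' Otherwise blocks are ordered by (number of expressed genes, then the
#' signature as a binary number) and colors are drawn deterministically
#' from the palette; identical inputs give byte-identical maps.
#'
#' @param partition A `signature_partition`.
#' @param palette Character vector of R colors, or `NULL` for the
#'   built-in colorblind-safe default.
#' @param explicit Optional named list/vector, signature key (e.g.
#'   `"110"`) -> color, overriding the palette.
#' @param seed Integer; kept for interface stability — the default
#'   assignment is already deterministic and does not consume
#'   randomness.
#' @param background_color Color for cells expressing no query gene.
#' @param context_color Color for context meshes.
#' @param context_opacity Opacity of context meshes in `[0,1]`.
#' @return A `color_map`: list with `entries` (signature key -> RGBA in
#'   `[0,1]`, 8-bit quantized), `background_color`, `context_color`
#'   (RGBA with `context_opacity` as alpha).
#' @export
assign_colors <- function(partition, palette = NULL, explicit = NULL, seed = 0L,
                          background_color = "grey80", context_color = "grey50",
                          context_opacity = 0.15) {
  stopifnot(inherits(partition, "signature_partition"))
  keys <- order_blocks(names(partition$blocks))
  if (!is.null(explicit)) {
    missing <- setdiff(keys, names(explicit))
    if (length(missing)) {
      stop("explicit color map misses signature block(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    entries <- lapply(keys, function(k) as_rgba(explicit[[k]]))
  } else {
    pal <- if (is.null(palette)) default_palette(length(keys)) else palette
    if (length(pal) < length(keys)) {
      stop("palette has ", length(pal), " colors for ", length(keys), " blocks",
           call. = FALSE)
    }
    entries <- lapply(seq_along(keys), function(i) as_rgba(pal[[i]]))
  }
  names(entries) <- keys
  ctx <- as_rgba(context_color)
  ctx[4] <- quantize8(c(0, 0, 0, context_opacity))[4]
  structure(
    list(entries = entries, background_color = as_rgba(background_color),
         context_color = ctx, seed = as.integer(seed)),
    class = "color_map"
  )
}

#' @export
print.color_map <- function(x, ...) {
  cat(sprintf("<color_map> %d block color(s)\n", length(x$entries)))
  for (k in names(x$entries)) cat("  ", k, " ", color_to_hex(x$entries[[k]]), "\n", sep = "")
  invisible(x)
}

#' Sender/receiver signaling overlay
#'
#' Colors a peptidergic (or other ligand/receptor) network: cells whose
#' class expresses the ligand gene only are senders, receptor-only
#' cells are receivers, cells expressing both get their own role (a
#' blend would be ambiguous against light backgrounds). The canonical
#' example is the neuropeptide flp-1, confined to the AVK head
#' interneuron pair, against its broadly expressed receptor frpr-7.
#'
#' @param table An `expression_table`.
#' @param ligand_gene,receptor_gene Gene symbols.
#' @param roster A `neuron_roster`.
#' @param min_value Strict expression cutoff.
#' @return Named character vector over all roster cells with values in
#'   `c("sender", "receiver", "both", "none")`.
#' @export
signaling_overlay <- function(table, ligand_gene, receptor_gene,
                              roster = load_roster(), min_value = 0) {
  if (tolower(trimws(ligand_gene)) == tolower(trimws(receptor_gene))) {
    # self-pair: every expressing cell is simultaneously sender and receiver
    sigs <- compute_signatures(table, ligand_gene, roster = roster,
                               min_value = min_value)
    return(vapply(sigs, function(b) if (b[1]) "both" else "none", ""))
  }
  sigs <- compute_signatures(table, c(ligand_gene, receptor_gene),
                             roster = roster, min_value = min_value)
  vapply(sigs, function(b) {
    if (b[1] && b[2]) "both" else if (b[1]) "sender" else if (b[2]) "receiver" else "none"
  }, "")
}

#' Default colors for signaling roles
#'
#' Dark red for senders, light blue for receivers, purple for cells in
#' both roles.
#'
#' @return Named list of RGBA colors keyed by role.
#' @export
role_colors <- function() {
  list(sender = as_rgba("darkred"), receiver = as_rgba("lightblue"),
       both = as_rgba("purple"))
}

#' Export a partition (or role overlay) as a tidy CSV
#'
#' One row per cell: `cell_name, class_name, signature_bits, color_hex,
#' role`. Background cells get empty color and role `"none"`.
#'
#' @param partition A `signature_partition`.
#' @param colormap A `color_map` for the partition.
#' @param roster A `neuron_roster`.
#' @param roles Optional named role vector from [signaling_overlay()].
#' @param path Optional output CSV path.
#' @return The data frame, invisibly if `path` is given.
#' @export
partition_to_csv <- function(partition, colormap, roster = load_roster(),
                             roles = NULL, path = NULL) {
  rows <- list()
  for (k in names(partition$blocks)) {
    hex <- color_to_hex(colormap$entries[[k]])
    for (cell in partition$blocks[[k]]) {
      rows[[cell]] <- data.frame(cell_name = cell, signature_bits = k,
                                 color_hex = hex, stringsAsFactors = FALSE)
    }
  }
  for (cell in partition$background) {
    rows[[cell]] <- data.frame(cell_name = cell,
                               signature_bits = strrep("0", length(partition$query_genes)),
                               color_hex = "", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$cell_name), ]
  df$class_name <- class_of_cell(roster, df$cell_name)
  df$role <- if (is.null(roles)) "" else unname(roles[df$cell_name])
  df <- df[, c("cell_name", "class_name", "signature_bits", "color_hex", "role")]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
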