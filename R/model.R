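#' 3D anatomical models
#'
#' An `anatomy_model` binds a neuron roster to geometry in the spirit of
#' the openworm.org Virtual Worm: one named mesh per individual neuron,
#' plus passive context meshes (body outline, pharynx) rendered
#' translucently for orientation. Mesh names are matched to roster cell
#' names case-insensitively, optionally after stripping a user-supplied
#' regex (model files often prefix names, e.g. `"WBneuron.AVKL"`).
#' Geometry is never re-axed: whatever coordinate frame the file uses is
#' preserved, and camera presets are defined from the bounding box.
#'
#' @name anatomy_model
#' @keywords internal
NULL

#' Load a 3D anatomy model
#'
#' @param path A `.obj` or `.gltf` file, or a directory of one-per-mesh
#'   `.ply` files.
#' @param roster A `neuron_roster` (defaults to the packaged
#'   hermaphrodite roster).
#' @param name_pattern Optional regex removed from mesh names before
#'   matching against cell names (e.g. `"^WBneuron\\\\."`).
#' @return An `anatomy_model`: list with `roster`, `neuron_meshes`
#'   (named by canonical cell name), `soma_positions` (cell x 3 matrix,
#'   centroid of the mesh's largest connected component),
#'   `context_meshes`, `frame` (free-text tag).
#' @export
load_model <- function(path, roster = load_roster(), name_pattern = NULL) {
  objects <- read_any_scene(path)
  build_anatomy_model(objects, roster, name_pattern = name_pattern,
                      frame = paste0("as-loaded:", basename(path)))
}

read_any_scene <- function(path) {
  if (dir.exists(path)) {
    plys <- list.files(path, pattern = "\\.ply$", full.names = TRUE)
    if (!length(plys)) stop("no .ply files in directory '", path, "'", call. = FALSE)
    return(do.call(c, lapply(sort(plys), read_ply)))
  }
  if (!file.exists(path)) stop("model path not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         gltf = read_gltf(path),
         ply = read_ply(path),
         stop("unsupported model format '.", ext, "' (use OBJ, glTF or PLY)",
              call. = FALSE))
}

build_anatomy_model <- function(objects, roster, name_pattern = NULL,
                                frame = "as-loaded") {
  nms <- names(objects)
  stripped <- if (is.null(name_pattern)) nms else gsub(name_pattern, "", nms)
  hit <- match(toupper(trimws(stripped)), toupper(roster$cells$cell_name))
  if (all(is.na(hit))) {
    stop("no mesh name matches any roster cell; wrong model file?", call. = FALSE)
  }
  neuron_meshes <- list(); context_meshes <- list()
  soma <- list()
  for (i in seq_along(objects)) {
    if (!is.na(hit[i])) {
      cell <- roster$cells$cell_name[hit[i]]
      neuron_meshes[[cell]] <- objects[[i]]$mesh
      soma[[cell]] <- largest_component_centroid(objects[[i]]$mesh)
    } else {
      context_meshes[[nms[i]]] <- objects[[i]]$mesh
    }
  }
  soma_positions <- do.call(rbind, soma)
  if (!is.null(soma_positions)) {
    colnames(soma_positions) <- c("x", "y", "z")
    if (any(!is.finite(soma_positions))) {
      stop("non-finite soma centroid in model", call. = FALSE)
    }
  }
  structure(
    list(roster = roster, neuron_meshes = neuron_meshes,
         soma_positions = soma_positions, context_meshes = context_meshes,
         frame = frame),
    class = "anatomy_model"
  )
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("<anatomy_model> %d neuron meshes, %d context meshes [%s]\n",
              length(x$neuron_meshes), length(x$context_meshes), x$frame))
  invisible(x)
}

#' Bounding box of all meshes in a model
#' @param model An `anatomy_model`.
#' @return 2 x 3 matrix (rows `min`, `max`).
#' @export
model_bbox <- function(model) {
  boxes <- lapply(c(model$neuron_meshes, model$context_meshes), mesh_bbox)
  mn <- apply(do.call(rbind, lapply(boxes, function(b) b["min", ])), 2, min)
  mx <- apply(do.call(rbind, lapply(boxes, function(b) b["max", ])), 2, max)
  out <- rbind(min = mn, max = mx)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Soma position of a cell
#' @param model An `anatomy_model`.
#' @param cell Cell name.
#' @return Length-3 numeric, or `NULL` if the cell has no mesh.
#' @export
soma_position <- function(model, cell) {
  sp <- model$soma_positions
  if (is.null(sp) || !(cell %in% rownames(sp))) return(NULL)
  sp[cell, ]
}
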