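#' Renderable scenes
#'
#' A `scene` binds an anatomy model to a color map: cells colored by
#' their signature block (or signaling role) get opaque materials,
#' uncolored neurons a neutral background material, and context meshes
#' (body, pharynx) a translucent material so neurons remain visible
#' through the body wall. Cells that have a known soma position but no
#' mesh are represented by soma-sphere stand-ins.
#'
#' @name scene
#' @keywords internal
NULL

#' Camera specification
#'
#' Presets are defined from the model bounding box, not from anatomical
#' axes, because model files keep their own coordinate frame: the long
#' body axis is taken to be the bounding-box axis with the largest
#' extent, "head" is its maximum end, "tail" its minimum end.
#'
#' @param preset One of `"whole_worm"`, `"head"`, `"midbody"`,
#'   `"tail"`, `"custom"`.
#' @param eye,target,up Length-3 vectors (required for `"custom"`).
#' @param fov Vertical field of view in degrees.
#' @param width,height Output resolution in pixels.
#' @param model An `anatomy_model`, required for non-custom presets.
#' @return A `camera_spec`.
#' @export
camera_spec <- function(preset = "custom", eye = NULL, target = NULL,
                        up = c(0, 1, 0), fov = 40, width = 320, height = 240,
                        model = NULL) {
  stopifnot(width >= 1, height >= 1, fov > 0, fov < 180)
  if (preset != "custom") {
    stopifnot(!is.null(model))
    bb <- model_bbox(model)
    ext <- bb["max", ] - bb["min", ]
    long <- which.max(ext)
    mid <- colMeans(bb)
    frac <- switch(preset,
                   whole_worm = c(0, 1), head = c(2 / 3, 1),
                   midbody = c(1 / 3, 2 / 3), tail = c(0, 1 / 3),
                   stop("unknown camera preset '", preset, "'", call. = FALSE))
    lo <- bb["min", long] + frac[1] * ext[long]
    hi <- bb["min", long] + frac[2] * ext[long]
    target <- mid
    target[long] <- (lo + hi) / 2
    # view from the axis with the smallest extent, so the long axis is on-screen
    side <- which.min(ext)
    if (side == long) side <- setdiff(1:3, long)[1]
    span <- max(hi - lo, max(ext[-long]), 1e-9)
    dist <- 1.2 * span / (2 * tan(fov / 2 * pi / 180))
    eye <- target
    eye[side] <- eye[side] + dist + ext[side] / 2
    upv <- c(0, 0, 0)
    upaxis <- setdiff(1:3, c(long, side))[1]
    upv[upaxis] <- 1
    up <- upv
  }
  stopifnot(!is.null(eye), !is.null(target))
  eye <- as.numeric(eye); target <- as.numeric(target)
  if (all(abs(eye - target) < 1e-12)) stop("camera eye must differ from target", call. = FALSE)
  structure(list(preset = preset, eye = eye, target = target,
                 up = as.numeric(up), fov = fov,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_spec")
}

#' Build a colorable scene
#'
#' @param model An `anatomy_model`.
#' @param colormap A `color_map` from [assign_colors()], or `NULL` for
#'   an all-neutral scene.
#' @param partition_or_roles A `signature_partition`, or a named role
#'   vector from [signaling_overlay()], or `NULL`.
#' @param neutral_color Material for neurons outside every block.
#' @param soma_radius Radius of soma-sphere stand-ins for colored cells
#'   that lack a mesh; default 1.5% of the bounding-box diagonal.
#' @param fallback_positions Optional matrix (rows named by cell) of
#'   soma positions for cells without meshes.
#' @return A `scene`: list with `model`, `colormap`, `objects` (draw
#'   list: context first, then neurons), `cell_colors` (named list of
#'   RGBA for colored cells), `camera` (unset until render).
#' @export
build_scene <- function(model, colormap = NULL, partition_or_roles = NULL,
                        neutral_color = "grey85", soma_radius = NULL,
                        fallback_positions = NULL) {
  stopifnot(inherits(model, "anatomy_model"))
  cell_colors <- list()
  if (inherits(partition_or_roles, "signature_partition")) {
    stopifnot(inherits(colormap, "color_map"))
    for (k in names(partition_or_roles$blocks)) {
      for (cell in partition_or_roles$blocks[[k]]) {
        cell_colors[[cell]] <- colormap$entries[[k]]
      }
    }
  } else if (!is.null(partition_or_roles)) {
    roles <- partition_or_roles
    rc <- role_colors()
    for (cell in names(roles)[roles != "none"]) {
      cell_colors[[cell]] <- rc[[roles[[cell]]]]
    }
  }
  known <- c(rownames(model$soma_positions), names(model$neuron_meshes),
             model$roster$cells$cell_name, rownames(fallback_positions))
  bad <- setdiff(names(cell_colors), known)
  if (length(bad)) {
    stop("colored cell(s) absent from model and roster: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  if (is.null(soma_radius)) {
    bb <- tryCatch(model_bbox(model), error = function(e) NULL)
    soma_radius <- if (is.null(bb)) 1 else 0.015 * sqrt(sum((bb["max", ] - bb["min", ])^2))
  }
  ctx_col <- if (is.null(colormap)) c(as_rgba("grey50")[1:3], 0.15) else colormap$context_color
  neutral <- as_rgba(neutral_color)

  objects <- list()
  for (nm in names(model$context_meshes)) {
    objects[[nm]] <- scene_object(nm, model$context_meshes[[nm]], ctx_col)
  }
  cells <- sort(unique(c(names(model$neuron_meshes), names(cell_colors))))
  for (cell in cells) {
    col <- if (!is.null(cell_colors[[cell]])) cell_colors[[cell]] else neutral
    mesh <- model$neuron_meshes[[cell]]
    if (is.null(mesh)) {
      pos <- soma_position(model, cell)
      if (is.null(pos) && !is.null(fallback_positions) &&
          cell %in% rownames(fallback_positions)) {
        pos <- fallback_positions[cell, ]
      }
      if (is.null(pos)) {
        stop("cell '", cell, "' has neither a mesh nor a soma position", call. = FALSE)
      }
      mesh <- sphere_mesh(pos, soma_radius)
    }
    objects[[cell]] <- scene_object(cell, mesh, col)
  }
  structure(
    list(model = model, colormap = colormap, objects = objects,
         cell_colors = cell_colors,
         neuron_names = cells, context_names = names(model$context_meshes),
         neutral_color = neutral),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d neuron object(s) (%d colored), %d context object(s)\n",
              length(x$neuron_names), length(x$cell_colors), length(x$context_names)))
  invisible(x)
}

#' Export a colored scene to disk
#'
#' Re-importing the written file recovers the identical cell-to-color
#' binding (colors are 8-bit quantized at scene build time, so the
#' round trip is exact).
#'
#' @param scene A `scene`.
#' @param path Output path; for `"ply"` a directory.
#' @param format `"gltf"`, `"obj"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
export_scene <- function(scene, path, format = c("gltf", "obj", "ply")) {
  format <- match.arg(format)
  switch(format,
         gltf = write_gltf(scene$objects, path),
         obj = write_obj(scene$objects, path),
         ply = write_ply_dir(scene$objects, path))
  invisible(path)
}

#' Identify the neuron nearest a 3D point
#'
#' The headless analogue of clicking a neuron in a viewport: returns
#' the visible neuron whose mesh surface is nearest `point` (distance 0
#' when the point is inside the mesh). Ties are broken
#' lexicographically by cell name.
#'
#' @param scene A `scene`.
#' @param point Length-3 numeric.
#' @return List with `cell` and `distance`.
#' @export
pick_neuron <- function(scene, point) {
  point <- as.numeric(point)
  cells <- sort(scene$neuron_names)
  if (!length(cells)) stop("scene has no visible neurons", call. = FALSE)
  best <- NULL; best_d <- Inf
  for (cell in cells) {
    d <- point_mesh_distance(point, scene$objects[[cell]]$mesh)
    if (d < best_d) { best_d <- d; best <- cell }   # strict <: earlier name wins ties
    if (best_d == 0) break
  }
  list(cell = best, distance = best_d)
}

#' Unproject a screen pixel to a world-space ray
#' @param spec A `camera_spec`.
#' @param px,py Pixel coordinates (origin top-left, 0-based centers).
#' @return List with `origin` and `direction` (unit).
#' @export
unproject_pixel <- function(spec, px, py) {
  ax <- camera_axes(spec)
  focal <- (spec$height / 2) / tan(spec$fov / 2 * pi / 180)
  xc <- (px + 0.5) - spec$width / 2
  yc <- spec$height / 2 - (py + 0.5)
  dir <- xc * ax$right + yc * ax$up + focal * ax$forward
  list(origin = spec$eye, direction = dir / sqrt(sum(dir^2)))
}

#' Identify the first neuron hit by a ray
#'
#' @param scene A `scene`.
#' @param origin,direction Ray origin and direction.
#' @return List with `cell` and `t` (distance along the ray), or `NULL`
#'   cell if nothing is hit.
#' @export
pick_neuron_ray <- function(scene, origin, direction) {
  cells <- sort(scene$neuron_names)
  if (!length(cells)) stop("scene has no visible neurons", call. = FALSE)
  best <- NULL; best_t <- Inf
  for (cell in cells) {
    t <- ray_mesh_tmin(origin, direction, scene$objects[[cell]]$mesh)
    if (is.finite(t) && t < best_t) { best_t <- t; best <- cell }
  }
  list(cell = best, t = if (is.null(best)) NA_real_ else best_t)
}

ray_mesh_tmin <- function(origin, dir, mesh) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- sweep(-A, 2, origin, `+`)
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & tt > 1e-9
  if (!any(hit)) Inf else min(tt[hit])
}
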