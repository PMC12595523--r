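#' Offscreen flat-shaded rendering
#'
#' A deterministic software rasterizer: perspective projection, z-buffer
#' hidden-surface removal, flat (unlit) per-object colors, no
#' anti-aliasing. With flat shading the set of distinct pixel colors in
#' a frame is a subset of the scene's material colors plus the
#' background, which makes renders testable pixel-for-pixel. Context
#' meshes are drawn first, alpha-blended over the background, and do
#' not occlude neurons — the flat-mode analogue of a translucent body
#' wall.
#'
#' @name rendering
#' @keywords internal
NULL

camera_axes <- function(spec) {
  f <- spec$target - spec$eye
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * spec$up[3] - f[3] * spec$up[2],
         f[3] * spec$up[1] - f[1] * spec$up[3],
         f[1] * spec$up[2] - f[2] * spec$up[1])
  rn <- sqrt(sum(r^2))
  if (rn < 1e-12) stop("camera up vector is parallel to the view direction", call. = FALSE)
  r <- r / rn
  u <- c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3], r[1] * f[2] - r[2] * f[1])
  list(forward = f, right = r, up = u)
}

# pixel coverage of a mesh: TRUE where any triangle projects, ignoring
# depth. Used for context meshes so a translucent body blends exactly
# once per pixel no matter how many of its faces the view ray crosses.
rasterize_coverage <- function(mesh, spec, ax) {
  env <- new.env()
  env$rgb <- array(0, dim = c(spec$height, spec$width, 3))
  env$zbuf <- matrix(Inf, spec$height, spec$width)
  rasterize_object(env, mesh, c(1, 1, 1, 1), spec, ax)
  env$rgb[, , 1] > 0
}

# rasterize one object's triangles into rgb (H x W x 3) and zbuf,
# modifying them in place via environment
rasterize_object <- function(env, mesh, color, spec, ax, write_z = TRUE, blend = FALSE) {
  W <- spec$width; H <- spec$height
  focal <- (H / 2) / tan(spec$fov / 2 * pi / 180)
  rel <- sweep(mesh$vertices, 2, spec$eye, `-`)
  xc <- rel %*% ax$right
  yc <- rel %*% ax$up
  zc <- rel %*% ax$forward
  near <- 1e-6
  sx <- focal * xc / zc + W / 2
  sy <- H / 2 - focal * yc / zc
  alpha <- color[4]
  for (fi in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[fi, ]
    if (any(zc[f] <= near)) next
    x <- sx[f]; y <- sy[f]; z <- zc[f]
    x0 <- max(1L, floor(min(x) + 0.5)); x1 <- min(W, ceiling(max(x) + 0.5))
    y0 <- max(1L, floor(min(y) + 0.5)); y1 <- min(H, ceiling(max(y) + 0.5))
    if (x0 > x1 || y0 > y1) next
    px <- (x0:x1) - 0.5; py <- (y0:y1) - 0.5
    PX <- matrix(px, length(py), length(px), byrow = TRUE)
    PY <- matrix(py, length(py), length(px))
    d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (abs(d) < 1e-12) next
    w1 <- ((y[2] - y[3]) * (PX - x[3]) + (x[3] - x[2]) * (PY - y[3])) / d
    w2 <- ((y[3] - y[1]) * (PX - x[3]) + (x[1] - x[3]) * (PY - y[3])) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    # perspective-correct depth from interpolated 1/z
    zinv <- w1 / z[1] + w2 / z[2] + w3 / z[3]
    depth <- 1 / zinv
    rows <- y0:y1; cols <- x0:x1
    sub_z <- env$zbuf[rows, cols, drop = FALSE]
    upd <- inside & depth < sub_z
    if (!any(upd)) next
    if (write_z) {
      sub_z[upd] <- depth[upd]
      env$zbuf[rows, cols] <- sub_z
    }
    for (ch in 1:3) {
      plane <- env$rgb[rows, cols, ch, drop = FALSE]
      dim(plane) <- dim(upd)
      plane[upd] <- if (blend) {
        (1 - alpha) * plane[upd] + alpha * color[ch]
      } else {
        color[ch]
      }
      env$rgb[rows, cols, ch] <- plane
    }
  }
}

#' Render a scene to a PNG image
#'
#' @param scene A `scene`.
#' @param spec A `camera_spec` giving viewpoint and resolution.
#' @param out_path Optional `.png` path.
#' @param background Background color.
#' @return The H x W x 3 image array in `[0,1]`, invisibly if
#'   `out_path` is given.
#' @export
render_scene <- function(scene, spec, out_path = NULL, background = "white") {
  stopifnot(inherits(scene, "scene"), inherits(spec, "camera_spec"))
  ax <- camera_axes(spec)
  bg <- as_rgba(background)
  env <- new.env()
  env$rgb <- array(rep(bg[1:3], each = spec$height * spec$width),
                   dim = c(spec$height, spec$width, 3))
  env$zbuf <- matrix(Inf, spec$height, spec$width)

  # context first: each context object alpha-blends once over the
  # background within its silhouette, and never occludes neurons
  for (nm in scene$context_names) {
    ob <- scene$objects[[nm]]
    mask <- rasterize_coverage(ob$mesh, spec, ax)
    a <- ob$color[4]
    for (ch in 1:3) {
      plane <- env$rgb[, , ch]
      plane[mask] <- (1 - a) * plane[mask] + a * ob$color[ch]
      env$rgb[, , ch] <- plane
    }
  }
  for (nm in sort(scene$neuron_names)) {
    ob <- scene$objects[[nm]]
    rasterize_object(env, ob$mesh, ob$color, spec, ax)
  }
  img <- env$rgb
  # snap to the 8-bit grid PNG will store, so array and file agree
  img <- round(img * 255) / 255
  if (!is.null(out_path)) {
    png::writePNG(img, out_path)
    return(invisible(img))
  }
  img
}

#' Render a turntable frame sequence
#'
#' Rotates the camera eye about the target around the camera's up axis
#' in `n` equal steps; frame 0 is the unrotated start camera. Frames
#' are written as `frame_000.png`, `frame_001.png`, ... Video encoding
#' is left to external tools.
#'
#' @param scene A `scene`.
#' @param spec Start `camera_spec`.
#' @param n Number of frames.
#' @param out_dir Output directory (created if absent).
#' @param background Background color.
#' @return Character vector of written file paths.
#' @export
render_turntable <- function(scene, spec, n, out_dir, background = "white") {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  up <- spec$up / sqrt(sum(spec$up^2))
  paths <- character(n)
  for (k in seq_len(n) - 1L) {
    ang <- 2 * pi * k / n
    rel <- spec$eye - spec$target
    # Rodrigues rotation of the eye about the up axis
    cr <- c(up[2] * rel[3] - up[3] * rel[2],
            up[3] * rel[1] - up[1] * rel[3],
            up[1] * rel[2] - up[2] * rel[1])
    rot <- rel * cos(ang) + cr * sin(ang) + up * sum(up * rel) * (1 - cos(ang))
    sp <- spec
    sp$eye <- spec$target + rot
    paths[k + 1] <- file.path(out_dir, sprintf("frame_%03d.png", k))
    render_scene(scene, sp, paths[k + 1], background = background)
  }
  paths
}
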