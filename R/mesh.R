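#' Triangle meshes and 3D file formats
#'
#' A mesh is a list with `vertices` (n x 3 numeric matrix) and `faces`
#' (m x 3 integer matrix, 1-based). Scene files hold a *named* list of
#' objects, each `list(name, mesh, color, opacity)` with `color` an
#' RGBA vector in `[0,1]`. Three interchange dialects are supported:
#' Wavefront OBJ with named `o` groups and an MTL material library,
#' glTF 2.0 with an embedded base64 buffer, and ASCII PLY with
#' per-vertex RGBA (one file per object). Colors are quantized to 8 bits
#' per channel on export in every format, so export/import round-trips
#' are exact after that quantization.
#'
#' @name mesh_io
#' @keywords internal
NULL

new_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(nrow(faces) == 0 || (min(faces) >= 1 && max(faces) <= nrow(vertices)))
  list(vertices = vertices, faces = faces)
}

quantize8 <- function(color) {
  stopifnot(length(color) %in% c(3, 4))
  if (length(color) == 3) color <- c(color, 1)
  round(pmin(pmax(color, 0), 1) * 255) / 255
}

color_to_hex <- function(color) {
  b <- round(pmin(pmax(color, 0), 1) * 255)
  sprintf("#%02X%02X%02X", b[1], b[2], b[3])
}

mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

# Centroid of the largest connected component (faces sharing a vertex
# are connected). Small models may store several blobs under one name;
# the soma is taken to be the biggest one.
largest_component_centroid <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv == 0) return(c(NA_real_, NA_real_, NA_real_))
  if (nrow(mesh$faces) == 0) return(colMeans(mesh$vertices))
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    a <- find(f[1]); b <- find(f[2]); c <- find(f[3])
    parent[b] <- a; parent[find(c)] <- a
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  big <- as.integer(names(which.max(table(roots))))
  colMeans(mesh$vertices[roots == big, , drop = FALSE])
}

scene_object <- function(name, mesh, color = c(0.7, 0.7, 0.7, 1), opacity = NULL) {
  color <- quantize8(color)
  if (!is.null(opacity)) color[4] <- quantize8(c(0, 0, 0, opacity))[4]
  list(name = name, mesh = mesh, color = color)
}

## ---------------------------------------------------------------- OBJ

#' Write scene objects to Wavefront OBJ + MTL
#'
#' One `o` group per object, one `newmtl` per distinct quantized RGBA
#' color. Alpha is written as the MTL `d` (dissolve) value.
#'
#' @param objects Named list of scene objects (see [mesh_io]).
#' @param path Output `.obj` path; the `.mtl` sits next to it.
#' @return `path`, invisibly.
#' @export
write_obj <- function(objects, path) {
  mtl_path <- sub("\\.obj$", ".mtl", path)
  colors <- unique(lapply(objects, `[[`, "color"))
  keys <- vapply(colors, function(c) paste(sprintf("%.6f", c), collapse = "_"), "")
  mtl_names <- sprintf("mat%03d", seq_along(colors))
  mtl <- character()
  for (i in seq_along(colors)) {
    c4 <- colors[[i]]
    mtl <- c(mtl, paste0("newmtl ", mtl_names[i]),
             sprintf("Kd %.6f %.6f %.6f", c4[1], c4[2], c4[3]),
             sprintf("d %.6f", c4[4]), "")
  }
  writeLines(mtl, mtl_path)

  lines <- c("# wormsight OBJ export", paste0("mtllib ", basename(mtl_path)))
  offset <- 0L
  for (nm in names(objects)) {
    ob <- objects[[nm]]
    key <- paste(sprintf("%.6f", ob$color), collapse = "_")
    lines <- c(lines, paste0("o ", ob$name),
               paste0("usemtl ", mtl_names[match(key, keys)]),
               sprintf("v %.9g %.9g %.9g",
                       ob$mesh$vertices[, 1], ob$mesh$vertices[, 2], ob$mesh$vertices[, 3]),
               sprintf("f %d %d %d",
                       ob$mesh$faces[, 1] + offset, ob$mesh$faces[, 2] + offset,
                       ob$mesh$faces[, 3] + offset))
    offset <- offset + nrow(ob$mesh$vertices)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ (named `o`/`g` groups, optional MTL colors)
#'
#' @param path `.obj` path.
#' @return Named list of scene objects; objects without a material get
#'   a neutral grey color.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  mtl <- list()
  mtllib <- sub("^mtllib\\s+", "", grep("^mtllib\\s", lines, value = TRUE))
  for (m in mtllib) {
    mp <- file.path(dirname(path), m)
    if (file.exists(mp)) mtl <- utils::modifyList(mtl, read_mtl(mp))
  }

  verts <- list(); obj_faces <- list(); obj_mat <- list()
  cur <- "default"; nvert <- 0L
  for (ln in lines) {
    if (startsWith(ln, "v ")) {
      verts[[length(verts) + 1L]] <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4])
      nvert <- nvert + 1L
    } else if (startsWith(ln, "o ") || startsWith(ln, "g ")) {
      cur <- trimws(substring(ln, 3))
    } else if (startsWith(ln, "usemtl")) {
      obj_mat[[cur]] <- trimws(sub("^usemtl\\s*", "", ln))
    } else if (startsWith(ln, "f ")) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]][-1]
      idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
      idx <- ifelse(idx < 0, nvert + idx + 1L, idx)
      # fan-triangulate polygons
      for (k in seq_len(length(idx) - 2)) {
        obj_faces[[cur]] <- c(obj_faces[[cur]], idx[c(1, k + 1, k + 2)])
      }
    }
  }
  if (!length(obj_faces)) stop("no faces found in OBJ '", path, "'", call. = FALSE)
  V <- do.call(rbind, verts)

  out <- list()
  for (nm in names(obj_faces)) {
    gf <- matrix(obj_faces[[nm]], ncol = 3, byrow = TRUE)
    used <- sort(unique(as.vector(gf)))
    remap <- match(gf, used)
    mesh <- new_mesh(V[used, , drop = FALSE], matrix(remap, ncol = 3))
    col <- c(0.7, 0.7, 0.7, 1)
    mn <- obj_mat[[nm]]
    if (!is.null(mn) && !is.null(mtl[[mn]])) col <- mtl[[mn]]
    out[[nm]] <- scene_object(nm, mesh, col)
  }
  out
}

read_mtl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mats <- list(); cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "newmtl")) {
      cur <- trimws(sub("^newmtl\\s*", "", ln))
      mats[[cur]] <- c(0.7, 0.7, 0.7, 1)
    } else if (!is.null(cur) && startsWith(ln, "Kd ")) {
      mats[[cur]][1:3] <- as.numeric(strsplit(ln, "\\s+")[[1]][2:4])
    } else if (!is.null(cur) && startsWith(ln, "d ")) {
      mats[[cur]][4] <- as.numeric(strsplit(ln, "\\s+")[[1]][2])
    }
  }
  mats
}

## --------------------------------------------------------------- glTF

#' Write scene objects to glTF 2.0
#'
#' Single-file `.gltf` with the vertex/index buffer embedded as a
#' base64 data URI. Each object becomes one node + mesh + material;
#' base colors go to `pbrMetallicRoughness.baseColorFactor` (quantized
#' to 8 bits per channel), translucent objects get `alphaMode "BLEND"`.
#'
#' @param objects Named list of scene objects.
#' @param path Output `.gltf` path.
#' @return `path`, invisibly.
#' @export
write_gltf <- function(objects, path) {
  buf <- raw()
  accessors <- list(); buffer_views <- list(); meshes <- list()
  nodes <- list(); materials <- list()
  align4 <- function(b) c(b, raw((4 - length(b) %% 4) %% 4))

  for (i in seq_along(objects)) {
    ob <- objects[[i]]
    V <- ob$mesh$vertices
    idx <- as.integer(t(ob$mesh$faces)) - 1L

    pos_bytes <- writeBin(as.numeric(t(V)), raw(), size = 4, endian = "little")
    buf <- align4(buf)
    buffer_views[[length(buffer_views) + 1]] <- list(
      buffer = 0, byteOffset = length(buf), byteLength = length(pos_bytes), target = 34962)
    buf <- c(buf, pos_bytes)
    pos_acc <- length(accessors)
    accessors[[pos_acc + 1]] <- list(
      bufferView = length(buffer_views) - 1, componentType = 5126,
      count = nrow(V), type = "VEC3",
      min = as.numeric(apply(V, 2, min)), max = as.numeric(apply(V, 2, max)))

    idx_bytes <- writeBin(idx, raw(), size = 4, endian = "little")
    buf <- align4(buf)
    buffer_views[[length(buffer_views) + 1]] <- list(
      buffer = 0, byteOffset = length(buf), byteLength = length(idx_bytes), target = 34963)
    buf <- c(buf, idx_bytes)
    idx_acc <- length(accessors)
    accessors[[idx_acc + 1]] <- list(
      bufferView = length(buffer_views) - 1, componentType = 5125,
      count = length(idx), type = "SCALAR")

    c4 <- quantize8(ob$color)
    materials[[i]] <- list(
      name = paste0(ob$name, "_mat"),
      pbrMetallicRoughness = list(
        baseColorFactor = as.numeric(c4), metallicFactor = 0, roughnessFactor = 1),
      doubleSided = TRUE)
    if (c4[4] < 1) materials[[i]]$alphaMode <- "BLEND"

    meshes[[i]] <- list(
      name = ob$name,
      primitives = list(list(
        attributes = list(POSITION = pos_acc), indices = idx_acc,
        material = i - 1, mode = 4)))
    nodes[[i]] <- list(name = ob$name, mesh = i - 1)
  }

  gltf <- list(
    asset = list(version = "2.0", generator = "wormsight"),
    scene = 0,
    scenes = list(list(nodes = as.list(seq_along(objects) - 1))),
    nodes = nodes, meshes = meshes, materials = materials,
    accessors = accessors, bufferViews = buffer_views,
    buffers = list(list(
      byteLength = length(buf),
      uri = paste0("data:application/octet-stream;base64,",
                   gsub("[\r\n]", "", jsonlite::base64_enc(buf))))))
  jsonlite::write_json(gltf, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a wormsight-dialect glTF 2.0 file
#'
#' Supports the subset [write_gltf()] emits: embedded data-URI buffer,
#' float32 positions, uint16/uint32 indices, per-primitive base colors.
#'
#' @param path `.gltf` path.
#' @return Named list of scene objects.
#' @export
read_gltf <- function(path) {
  g <- jsonlite::read_json(path)
  uri <- g$buffers[[1]]$uri
  b64 <- sub("^data:.*;base64,", "", uri)
  buf <- jsonlite::base64_dec(b64)

  read_accessor <- function(ai) {
    acc <- g$accessors[[ai + 1]]
    bv <- g$bufferViews[[acc$bufferView + 1]]
    off <- (if (is.null(bv$byteOffset)) 0 else bv$byteOffset) +
      (if (is.null(acc$byteOffset)) 0 else acc$byteOffset)
    n_comp <- switch(acc$type, SCALAR = 1, VEC3 = 3, VEC4 = 4)
    n <- acc$count * n_comp
    bytes <- switch(as.character(acc$componentType), "5126" = 4, "5125" = 4, "5123" = 2)
    slice <- buf[(off + 1):(off + n * bytes)]
    if (acc$componentType == 5126) {
      readBin(slice, numeric(), n = n, size = 4, endian = "little")
    } else {
      readBin(slice, integer(), n = n, size = bytes, endian = "little",
              signed = bytes == 4)
    }
  }

  out <- list()
  for (mi in seq_along(g$meshes)) {
    m <- g$meshes[[mi]]
    prim <- m$primitives[[1]]
    pos <- read_accessor(prim$attributes$POSITION)
    idx <- read_accessor(prim$indices)
    mesh <- new_mesh(matrix(pos, ncol = 3, byrow = TRUE),
                     matrix(idx + 1L, ncol = 3, byrow = TRUE))
    col <- c(0.7, 0.7, 0.7, 1)
    if (!is.null(prim$material)) {
      mat <- g$materials[[prim$material + 1]]
      bc <- mat$pbrMetallicRoughness$baseColorFactor
      if (!is.null(bc)) col <- unlist(bc)
    }
    nm <- if (is.null(m$name)) paste0("mesh", mi) else m$name
    out[[nm]] <- scene_object(nm, mesh, col)
  }
  out
}

## ---------------------------------------------------------------- PLY

#' Write scene objects as ASCII PLY (one file per object)
#'
#' PLY carries a single mesh per file, so a scene is written as a
#' directory of `<name>.ply` files with per-vertex 8-bit RGBA.
#'
#' @param objects Named list of scene objects.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ply_dir <- function(objects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ob in objects) {
    write_ply(ob$mesh, file.path(dir, paste0(ob$name, ".ply")), color = ob$color)
  }
  invisible(dir)
}

write_ply <- function(mesh, path, color = c(0.7, 0.7, 0.7, 1)) {
  rgba <- round(quantize8(color) * 255)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format ascii 1.0", "comment wormsight",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green", "property uchar blue",
              "property uchar alpha",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g %d %d %d %d",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                rgba[1], rgba[2], rgba[3], rgba[4])
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path `.ply` path.
#' @return A scene object named after the file stem; color is the first
#'   vertex's RGBA if present.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not a PLY file: ", path, call. = FALSE)
  header <- lines[1:end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vprops <- sub("^property\\s+\\S+\\s+", "",
                grep("^property (float|uchar|double) ", header[seq_len(
                  match(grep("^element face", header)[1], seq_along(header)))], value = TRUE))
  vlines <- lines[(end + 1):(end + nv)]
  vm <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), as.numeric))
  colnames(vm) <- vprops[seq_len(ncol(vm))]
  V <- vm[, c("x", "y", "z"), drop = FALSE]
  col <- c(0.7, 0.7, 0.7, 1)
  if (all(c("red", "green", "blue") %in% colnames(vm))) {
    col[1:3] <- vm[1, c("red", "green", "blue")] / 255
    if ("alpha" %in% colnames(vm)) col[4] <- vm[1, "alpha"] / 255
  }
  flines <- lines[(end + nv + 1):(end + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(t) as.integer(t[2:4]) + 1L))
  nm <- tools::file_path_sans_ext(basename(path))
  stats::setNames(list(scene_object(nm, new_mesh(V, fm), col)), nm)
}
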