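## Triangle-mesh container and plain-text I/O (ASCII STL, OBJ, ASCII PLY).
## Only triangle soups are supported: that is all the slicing step needs.

#' Triangle mesh
#'
#' A minimal triangle-mesh container: an `n x 3` vertex matrix (mm) and an
#' `m x 3` integer face matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix, `n x 3`, coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @return an object of class `cranio_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3 || any(!is.finite(vertices)))
    cranio_abort("cranio_input_error", "vertices must be a finite n x 3 matrix")
  if (ncol(faces) != 3 || any(faces < 1L) || any(faces > nrow(vertices)))
    cranio_abort("cranio_input_error", "faces must index existing vertices")
  structure(list(vertices = vertices, faces = faces), class = "cranio_mesh")
}

#' @export
print.cranio_mesh <- function(x, ...) {
  cat(sprintf("cranio_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Centroid of mesh vertices
#'
#' Used as the default superior-side hint when orienting the cutting plane.
#'
#' @param mesh a `cranio_mesh`.
#' @return length-3 numeric vector.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Apply an affine map to a mesh
#'
#' @param mesh a `cranio_mesh`.
#' @param rotation 3 x 3 matrix applied to each vertex (default identity).
#' @param translation length-3 vector added after rotation.
#' @param scale scalar isotropic scale applied before rotation.
#' @return transformed `cranio_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- (mesh$vertices * scale) %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_mesh(v, mesh$faces)
}

#' Mirror a mesh and its landmarks across the mid-sagittal plane
#'
#' Reflects y -> -y (patient left/right swap) and reverses face winding so
#' the surface stays consistently oriented; landmark left/right names are
#' swapped accordingly.
#'
#' @param mesh a `cranio_mesh`.
#' @param landmarks optional `cranio_landmarks` to mirror alongside.
#' @return the mirrored mesh, or `list(mesh=, landmarks=)` when landmarks
#'   are supplied.
#' @export
mirror_mesh <- function(mesh, landmarks = NULL) {
  v <- mesh$vertices
  v[, 2] <- -v[, 2]
  m <- tri_mesh(v, mesh$faces[, c(1L, 3L, 2L)])
  if (is.null(landmarks)) return(m)
  refl <- function(p) if (is.null(p)) NULL else c(p[1], -p[2], p[3])
  lm <- landmark_set(
    ex_left = refl(landmarks$ex_right), ex_right = refl(landmarks$ex_left),
    po_left = refl(landmarks$po_right), po_right = refl(landmarks$po_left)
  )
  list(mesh = m, landmarks = lm)
}

#' Read a triangle mesh (ASCII STL, OBJ or ASCII PLY)
#'
#' Format is chosen from the file extension. STL facets are welded on exact
#' vertex coordinates so shared edges are recovered.
#'
#' @param path file path ending in .stl, .obj or .ply.
#' @return a `cranio_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    cranio_abort("cranio_input_error", paste("mesh file not found:", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .read_stl(path),
    obj = .read_obj(path),
    ply = .read_ply(path),
    cranio_abort("cranio_input_error",
                 paste("unsupported mesh format:", ext))
  )
}

#' Write a triangle mesh (ASCII STL, OBJ or ASCII PLY)
#'
#' @param mesh a `cranio_mesh`.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .write_stl(mesh, path),
    obj = .write_obj(mesh, path),
    ply = .write_ply(mesh, path),
    cranio_abort("cranio_input_error",
                 paste("unsupported mesh format:", ext))
  )
  invisible(path)
}

.read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(head), "solid"))
    cranio_abort("cranio_input_error", "only ASCII STL is supported")
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    cranio_abort("cranio_input_error", "malformed STL: vertex count not divisible by 3")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  key <- apply(nums, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  tri_mesh(nums[uniq, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

.write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid craniocurve", con)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  n <- .cross3(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  blocks <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(blocks, con)
  writeLines("endsolid craniocurve", con)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    cranio_abort("cranio_input_error", "malformed OBJ: no vertices or faces")
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(tok) {
    ix <- as.integer(sub("/.*$", "", tok[-1]))
    if (length(ix) != 3L)
      cranio_abort("cranio_input_error", "OBJ faces must be triangles")
    ix
  }))
  tri_mesh(verts, faces)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1]), "ply") || !grepl("ascii", lines[2]))
    cranio_abort("cranio_input_error", "only ASCII PLY is supported")
  hdr_end <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(tok) as.numeric(tok[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(tok) {
    if (as.integer(tok[1]) != 3L)
      cranio_abort("cranio_input_error", "PLY faces must be triangles")
    as.integer(tok[2:4]) + 1L
  }))
  tri_mesh(verts, faces)
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

## row-wise cross product of n x 3 matrices
.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
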