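## Landmark handling and the landmark-defined cutting planes.
##
## The base plane is spanned by three external landmarks: left and right
## exocanthion plus one porion (the left by convention; the right in
## left-sided anterior plagiocephaly, where the left side is deformed).
## The analysis plane sits 40 mm above the base plane along its normal.

#' External landmark set
#'
#' The four external soft-tissue landmarks used to anchor the cutting plane:
#' left/right exocanthion (outer eye corner) and left/right porion (upper
#' margin of the external auditory meatus), as 3-D points in mm. `po_right`
#' may be omitted when unused.
#'
#' @param ex_left,ex_right,po_left,po_right length-3 numeric vectors (mm);
#'   `po_left`/`po_right` may individually be `NULL` but at least one porion
#'   must be present.
#' @return an object of class `cranio_landmarks`.
#' @export
landmark_set <- function(ex_left, ex_right, po_left = NULL, po_right = NULL) {
  chk <- function(p, name) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 3 || any(!is.finite(p)))
      cranio_abort("cranio_input_error",
                   paste0("landmark '", name, "' must be 3 finite coordinates"))
    p
  }
  ex_left <- chk(ex_left, "ex_left"); ex_right <- chk(ex_right, "ex_right")
  po_left <- chk(po_left, "po_left"); po_right <- chk(po_right, "po_right")
  if (is.null(ex_left) || is.null(ex_right))
    cranio_abort("cranio_input_error", "both exocanthion landmarks are required")
  if (is.null(po_left) && is.null(po_right))
    cranio_abort("cranio_input_error", "at least one porion landmark is required")
  if (sqrt(sum((ex_left - ex_right)^2)) < 1e-12)
    cranio_abort("cranio_degenerate_landmarks", "ex_left and ex_right coincide")
  structure(list(ex_left = ex_left, ex_right = ex_right,
                 po_left = po_left, po_right = po_right),
            class = "cranio_landmarks")
}

#' @export
print.cranio_landmarks <- function(x, ...) {
  cat("cranio_landmarks [mm]:\n")
  for (nm in c("ex_left", "ex_right", "po_left", "po_right")) {
    p <- x[[nm]]
    if (is.null(p)) cat(sprintf("  %-9s <absent>\n", nm))
    else cat(sprintf("  %-9s (%.2f, %.2f, %.2f)\n", nm, p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Read landmarks from JSON or CSV
#'
#' JSON: an object with keys ex_left, ex_right, po_left, po_right, each a
#' 3-vector in mm. CSV: columns `name,x,y,z`. Names are case-insensitive.
#'
#' @param path path to a .json or .csv landmark file.
#' @return a `cranio_landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    cranio_abort("cranio_input_error", paste("landmark file not found:", path))
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    raw <- jsonlite::fromJSON(path)
    stats::setNames(lapply(raw, as.numeric), tolower(names(raw)))
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      cranio_abort("cranio_input_error", "landmark CSV needs columns name,x,y,z")
    stats::setNames(lapply(seq_len(nrow(df)), function(i)
      c(df$x[i], df$y[i], df$z[i])), tolower(df$name))
  } else {
    cranio_abort("cranio_input_error", paste("unsupported landmark format:", ext))
  }
  g <- function(nm) if (nm %in% names(vals)) vals[[nm]] else NULL
  landmark_set(ex_left = g("ex_left"), ex_right = g("ex_right"),
               po_left = g("po_left"), po_right = g("po_right"))
}

#' Write landmarks to JSON
#'
#' @param landmarks a `cranio_landmarks`.
#' @param path output .json path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  keep <- Filter(Negate(is.null), unclass(landmarks))
  jsonlite::write_json(keep, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

.normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12)
    cranio_abort("cranio_degenerate_landmarks", "zero-length direction vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the landmark-defined base cutting plane
#'
#' The plane through left/right exocanthion and the chosen porion. The
#' normal is oriented toward the superior side using `superior_hint` (any
#' point on the head's superior side, typically the mesh centroid). The
#' in-plane `u_axis` points anterior: it is the in-plane projection of the
#' vector from the porion used to the exocanthion midpoint. `v_axis`
#' completes a right-handed frame (`u x v = normal`), so `+v` points toward
#' the patient's left when the normal points superiorly.
#'
#' @param landmarks a `cranio_landmarks`.
#' @param side_of_porion `"left"` (default) or `"right"`; the right porion
#'   is conventionally used only for left-sided anterior plagiocephaly. The
#'   choice is an explicit input, never auto-detected.
#' @param superior_hint length-3 point on the superior side of the plane,
#'   or `NULL` to keep the raw cross-product orientation.
#' @return a `cranio_plane`: list with `origin`, `normal`, `u_axis`,
#'   `v_axis` (all length-3, axes orthonormal).
#' @export
build_base_plane <- function(landmarks, side_of_porion = c("left", "right"),
                             superior_hint = NULL) {
  side_of_porion <- match.arg(side_of_porion)
  po <- if (side_of_porion == "left") landmarks$po_left else landmarks$po_right
  if (is.null(po))
    cranio_abort("cranio_input_error",
                 paste0("porion '", side_of_porion, "' not present in landmark set"))
  a <- landmarks$ex_left; b <- landmarks$ex_right
  n_raw <- .cross(b - a, po - a)
  area <- sqrt(sum(n_raw^2)) / 2
  if (area <= 1e-6)
    cranio_abort("cranio_degenerate_landmarks",
                 sprintf("plane landmarks are (near-)collinear (triangle area %.3g mm^2)", area))
  normal <- n_raw / sqrt(sum(n_raw^2))
  origin <- (a + b) / 2
  if (!is.null(superior_hint) && sum(normal * (superior_hint - origin)) < 0)
    normal <- -normal
  ant <- origin - po                      # toward the eyes = anterior
  ant_in <- ant - sum(ant * normal) * normal
  u_axis <- .normalize3(ant_in)
  v_axis <- .cross(normal, u_axis)
  structure(list(origin = origin, normal = normal,
                 u_axis = u_axis, v_axis = v_axis,
                 side_of_porion = side_of_porion),
            class = "cranio_plane")
}

#' @export
print.cranio_plane <- function(x, ...) {
  cat(sprintf("cranio_plane: origin (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  normal (%.4f, %.4f, %.4f)  u (%.4f, %.4f, %.4f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$u_axis[1], x$u_axis[2], x$u_axis[3]))
  invisible(x)
}

#' Offset a plane along its normal
#'
#' @param plane a `cranio_plane`.
#' @param height displacement in mm along the normal (default 40, i.e. the
#'   4 cm analysis height).
#' @return a parallel `cranio_plane` with unchanged axes.
#' @export
offset_plane <- function(plane, height = 40) {
  if (!is.finite(height))
    cranio_abort("cranio_input_error", "plane offset must be finite")
  plane$origin <- plane$origin + height * plane$normal
  plane
}

#' Project points into plane coordinates
#'
#' Maps 3-D points to in-plane `(u, v)` mm coordinates; any out-of-plane
#' component is dropped.
#'
#' @param p length-3 vector or `n x 3` matrix of points.
#' @param plane a `cranio_plane`.
#' @return length-2 vector or `n x 2` matrix.
#' @export
to_plane_coords <- function(p, plane) {
  one <- is.null(dim(p))
  p <- rbind(p)
  d <- sweep(p, 2, plane$origin)
  uv <- cbind(d %*% plane$u_axis, d %*% plane$v_axis)
  colnames(uv) <- c("u", "v")
  if (one) uv[1, ] else uv
}

#' Lift plane coordinates back to 3-D
#'
#' Inverse of [to_plane_coords()] for in-plane points.
#'
#' @param uv length-2 vector or `n x 2` matrix of `(u, v)` mm coordinates.
#' @param plane a `cranio_plane`.
#' @return length-3 vector or `n x 3` matrix.
#' @export
from_plane_coords <- function(uv, plane) {
  one <- is.null(dim(uv))
  uv <- rbind(uv)
  p <- outer(uv[, 1], plane$u_axis) + outer(uv[, 2], plane$v_axis)
  p <- sweep(p, 2, plane$origin, "+")
  if (one) p[1, ] else p
}
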