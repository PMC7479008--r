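## Mesh-plane slicing and the skull-outline polygon.
##
## The mesh is cut by the analysis plane; cut triangles each contribute one
## segment, and segments are chained into closed loops by the mesh edge each
## endpoint lies on. The loop with the largest enclosed area is the skull
## outline (any smaller loops - ears, noise blobs - are discarded).

#' Skull outline polygon
#'
#' A closed, ordered polygon of `(u, v)` points (mm) in cutting-plane
#' coordinates. Closure is implicit (the first vertex is not repeated).
#'
#' @param vertices `n x 2` numeric matrix (n >= 3), ordered
#'   counter-clockwise in `(u, v)`.
#' @param plane the `cranio_plane` the outline lives in (optional for
#'   outlines loaded from CSV).
#' @return an object of class `cranio_outline`.
#' @export
outline <- function(vertices, plane = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || any(!is.finite(vertices)))
    cranio_abort("cranio_degenerate_outline",
                 "outline needs >= 3 finite (u,v) vertices")
  if (.polygon_area(vertices) < 0) vertices <- vertices[nrow(vertices):1, ]
  if (abs(.polygon_area(vertices)) < 1e-9)
    cranio_abort("cranio_degenerate_outline", "outline encloses zero area")
  structure(list(vertices = vertices, plane = plane), class = "cranio_outline")
}

#' @export
print.cranio_outline <- function(x, ...) {
  cat(sprintf("cranio_outline: %d vertices, area %.1f mm^2\n",
              nrow(x$vertices), .polygon_area(x$vertices)))
  invisible(x)
}

## signed area, shoelace formula (positive = counter-clockwise)
.polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Slice a triangle mesh with a cutting plane
#'
#' Intersects every triangle with the plane (vertices lying exactly on the
#' plane are perturbed by 1e-9 mm to avoid degenerate coplanar cases),
#' chains the resulting segments into closed loops via shared mesh edges,
#' and returns the loop with the largest enclosed area, ordered
#' counter-clockwise in plane coordinates.
#'
#' @param mesh a `cranio_mesh`, closed around the vault at the plane height.
#' @param plane a `cranio_plane`.
#' @return a `cranio_outline`.
#' @export
slice_surface <- function(mesh, plane) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector(sweep(v, 2, plane$origin) %*% plane$normal)
  d[abs(d) < 1e-9] <- 1e-9                 # on-plane vertex perturbation
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  cut <- (pmax(d1, d2, d3) > 0) & (pmin(d1, d2, d3) < 0)
  if (!any(cut))
    cranio_abort("cranio_empty_slice", "plane does not intersect the mesh")
  fc <- f[cut, , drop = FALSE]
  dc <- cbind(d1[cut], d2[cut], d3[cut])

  ## per triangle, the two edges whose endpoints straddle the plane
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  pts <- vector("list", 3L)
  keys <- vector("list", 3L)
  hit <- matrix(FALSE, nrow(fc), 3L)
  for (e in 1:3) {
    i <- edge_pairs[[e]][1]; j <- edge_pairs[[e]][2]
    hit[, e] <- dc[, i] * dc[, j] < 0
    ai <- fc[, i]; aj <- fc[, j]
    t <- dc[, i] / (dc[, i] - dc[, j])
    p <- v[ai, , drop = FALSE] + t * (v[aj, , drop = FALSE] - v[ai, , drop = FALSE])
    pts[[e]] <- p
    keys[[e]] <- paste0(pmin(ai, aj), "_", pmax(ai, aj))
  }
  ## each cut triangle has exactly two straddling edges
  seg_key <- matrix(NA_character_, nrow(fc), 2L)
  seg_pt <- array(NA_real_, c(nrow(fc), 2L, 3L))
  slot <- rep(1L, nrow(fc))
  for (e in 1:3) {
    rows <- which(hit[, e])
    for (r in rows) {
      seg_key[r, slot[r]] <- keys[[e]][r]
      seg_pt[r, slot[r], ] <- pts[[e]][r, ]
      slot[r] <- slot[r] + 1L
    }
  }
  ok <- slot == 3L
  seg_key <- seg_key[ok, , drop = FALSE]
  seg_pt <- seg_pt[ok, , , drop = FALSE]
  if (!nrow(seg_key))
    cranio_abort("cranio_empty_slice", "plane does not intersect the mesh")

  loops <- .chain_segments(seg_key, seg_pt)
  if (!length(loops$closed)) {
    if (length(loops$open))
      cranio_abort("cranio_open_contour",
                   "slice produced only open polylines (mesh not closed at this height)")
    cranio_abort("cranio_empty_slice", "no usable intersection loop")
  }
  uv_loops <- lapply(loops$closed, function(P) to_plane_coords(P, plane))
  areas <- vapply(uv_loops, function(uv) abs(.polygon_area(uv)), 0)
  outline(uv_loops[[which.max(areas)]], plane = plane)
}

## Chain segments whose endpoints are identified by mesh-edge keys.
## Returns closed loops as matrices of 3-D points (one row per segment).
.chain_segments <- function(seg_key, seg_pt) {
  nseg <- nrow(seg_key)
  all_keys <- unique(as.vector(seg_key))
  k1 <- match(seg_key[, 1], all_keys)
  k2 <- match(seg_key[, 2], all_keys)
  ## adjacency: for each edge key, the segments touching it
  touch <- vector("list", length(all_keys))
  for (s in seq_len(nseg)) {
    touch[[k1[s]]] <- c(touch[[k1[s]]], s)
    touch[[k2[s]]] <- c(touch[[k2[s]]], s)
  }
  used <- logical(nseg)
  closed <- list(); open <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    path_pts <- list(seg_pt[s0, 1, ], seg_pt[s0, 2, ])
    used[s0] <- TRUE
    start_key <- k1[s0]; cur_key <- k2[s0]
    repeat {
      nxt <- touch[[cur_key]][!used[touch[[cur_key]]]]
      if (!length(nxt)) break
      s <- nxt[1]
      used[s] <- TRUE
      if (k1[s] == cur_key) {
        path_pts[[length(path_pts) + 1L]] <- seg_pt[s, 2, ]
        cur_key <- k2[s]
      } else {
        path_pts[[length(path_pts) + 1L]] <- seg_pt[s, 1, ]
        cur_key <- k1[s]
      }
      if (cur_key == start_key) break
    }
    P <- do.call(rbind, path_pts)
    if (cur_key == start_key && nrow(P) > 3) {
      closed[[length(closed) + 1L]] <- P[-nrow(P), , drop = FALSE]
    } else {
      open[[length(open) + 1L]] <- P
    }
  }
  list(closed = closed, open = open)
}

#' Area centroid of an outline
#'
#' Centroid of the enclosed region by the polygon-area (shoelace) formula -
#' not the vertex mean, so it is independent of vertex density along edges.
#'
#' @param outline a `cranio_outline`.
#' @return length-2 `(u, v)` in mm.
#' @export
area_centroid <- function(outline) {
  v <- outline$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9)
    cranio_abort("cranio_degenerate_outline", "outline encloses zero area")
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

## even-odd point-in-polygon test
.point_in_polygon <- function(pt, v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2L == 1L
}

#' Locate the occipital start point of the polar curve
#'
#' Projects the two exocanthion landmarks into the outline's plane, takes
#' the perpendicular bisector of the projected ex-ex segment, and of its
#' intersections with the outline keeps the posterior one (negative
#' anterior-axis component relative to the ex midpoint; farther from the ex
#' midpoint when several qualify). That point is the occipital start of the
#' curve. The angular sweep direction is chosen so the projected right
#' exocanthion is passed in the first half-turn, i.e. the curve runs past
#' the patient's right side first.
#'
#' @param outline a `cranio_outline` with its `plane` set (or pass
#'   projected 2-D ex points via `ex_uv`).
#' @param landmarks a `cranio_landmarks`; ignored when `ex_uv` is given.
#' @param ex_uv optional 2 x 2 matrix of projected `(u, v)` coordinates,
#'   rows = ex_left, ex_right; used for mesh-free outlines.
#' @return a `cranio_frame`: list with `center` (area centroid),
#'   `start_point`, `start_direction` (unit 2-vector) and
#'   `right_first_sign` (+1 or -1).
#' @export
locate_start <- function(outline, landmarks = NULL, ex_uv = NULL) {
  if (is.null(ex_uv)) {
    if (is.null(outline$plane) || is.null(landmarks))
      cranio_abort("cranio_input_error",
                   "need landmarks + outline plane, or explicit ex_uv")
    ex_uv <- rbind(to_plane_coords(landmarks$ex_left, outline$plane),
                   to_plane_coords(landmarks$ex_right, outline$plane))
  }
  exl <- ex_uv[1, ]; exr <- ex_uv[2, ]
  if (sqrt(sum((exl - exr)^2)) < 1e-9)
    cranio_abort("cranio_degenerate_landmarks",
                 "projected exocanthion points coincide")
  mid <- (exl + exr) / 2
  along <- exr - exl
  bis <- c(-along[2], along[1])
  bis <- bis / sqrt(sum(bis^2))

  ## all intersections of the (infinite) bisector line with polygon edges:
  ## signed side of each vertex w.r.t. the line, zeros counted as positive
  ## so vertices lying exactly on the line yield exactly one crossing
  v <- outline$vertices
  cr <- (v[, 1] - mid[1]) * bis[2] - (v[, 2] - mid[2]) * bis[1]
  pos <- cr >= 0
  nxt <- c(2:nrow(v), 1L)
  hit <- which(pos != pos[nxt])
  if (!length(hit))
    cranio_abort("cranio_start_not_found",
                 "ex-ex perpendicular bisector does not intersect the outline")
  sfrac <- cr[hit] / (cr[hit] - cr[nxt][hit])
  pts <- v[hit, , drop = FALSE] +
    sfrac * (v[nxt, , drop = FALSE][hit, , drop = FALSE] - v[hit, , drop = FALSE])

  ## posterior = negative component along the anterior axis (u), i.e. the
  ## intersection on the occiput side of the ex midpoint
  anterior <- c(1, 0)
  comp <- (pts[, 1] - mid[1]) * anterior[1] + (pts[, 2] - mid[2]) * anterior[2]
  post <- which(comp < 0)
  if (!length(post))
    cranio_abort("cranio_start_not_found",
                 "no posterior intersection of the bisector with the outline")
  dist2 <- (pts[post, 1] - mid[1])^2 + (pts[post, 2] - mid[2])^2
  start <- pts[post[which.max(dist2)], ]

  center <- area_centroid(outline)
  if (!.point_in_polygon(center, v))
    cranio_abort("cranio_center_outside", "outline centroid lies outside the polygon")
  sd <- start - center
  nsd <- sqrt(sum(sd^2))
  if (nsd < 1e-9)
    cranio_abort("cranio_start_not_found", "start point coincides with centroid")
  sd <- sd / nsd

  ## sweep orientation: pass the projected right ex within the first 180 deg
  w <- exr - center
  ang <- atan2(sd[1] * w[2] - sd[2] * w[1], sd[1] * w[1] + sd[2] * w[2])
  ang <- (ang * 180 / pi) %% 360
  sign <- if (ang > 0 && ang < 180) 1 else -1
  structure(list(center = center, start_point = start,
                 start_direction = sd, right_first_sign = sign),
            class = "cranio_frame")
}

#' @export
print.cranio_frame <- function(x, ...) {
  cat(sprintf(
    "cranio_frame: center (%.2f, %.2f), start (%.2f, %.2f), sweep %s\n",
    x$center[1], x$center[2], x$start_point[1], x$start_point[2],
    if (x$right_first_sign > 0) "+1 (ccw)" else "-1 (cw)"))
  invisible(x)
}

#' Read / write outline CSV
#'
#' Two columns `u_mm,v_mm`, one ordered vertex per row: the mesh-free entry
#' point for outlines obtained elsewhere (e.g. 3-D photogrammetry).
#'
#' @param path CSV path.
#' @return `read_outline_csv`: a `cranio_outline` (no plane attached).
#' @export
read_outline_csv <- function(path) {
  if (!file.exists(path))
    cranio_abort("cranio_input_error", paste("outline file not found:", path))
  df <- utils::read.csv(path)
  if (!all(c("u_mm", "v_mm") %in% names(df)))
    cranio_abort("cranio_input_error", "outline CSV needs columns u_mm,v_mm")
  outline(cbind(df$u_mm, df$v_mm))
}

#' @rdname read_outline_csv
#' @param outline a `cranio_outline` to write.
#' @export
write_outline_csv <- function(outline, path) {
  utils::write.csv(data.frame(u_mm = outline$vertices[, 1],
                              v_mm = outline$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
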