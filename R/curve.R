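## The polar "sinusoid" curve: 360 radii sampled from the outline centroid,
## starting at the occiput and sweeping past the patient's right side first,
## then normalized by the mean radius so 1.0 is the average radius. The
## normalization makes curves comparable across head sizes and ages.

#' Sample absolute polar radii from an outline
#'
#' For each integer-degree angle from the occipital start direction
#' (sweeping in the frame's `right_first_sign` orientation), casts a ray
#' from the centroid and takes the outermost exact ray-segment intersection
#' with the polygon boundary. For star-shaped outlines every ray crosses the
#' boundary exactly once; when a ray crosses more than once (non-star
#' outline) the outermost distance is used and a warning is raised once.
#'
#' @param outline a `cranio_outline`.
#' @param frame a `cranio_frame` from [locate_start()].
#' @param n_samples number of equally spaced angles (default 360, one per
#'   degree - the resolution all curve features are defined on).
#' @return numeric vector of `n_samples` radii in mm, angle `theta_deg` as
#'   an attribute.
#' @export
polar_sample <- function(outline, frame, n_samples = 360) {
  v <- outline$vertices
  C <- frame$center
  if (!.point_in_polygon(C, v))
    cranio_abort("cranio_center_outside", "curve center lies outside the outline")
  theta <- (seq_len(n_samples) - 1) * 360 / n_samples
  ang <- frame$right_first_sign * theta * pi / 180
  sd <- frame$start_direction
  ## rotate start_direction by +/- theta
  dir_u <- cos(ang) * sd[1] - sin(ang) * sd[2]
  dir_v <- sin(ang) * sd[1] + cos(ang) * sd[2]

  p <- v
  q <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  eu <- q[, 1] - p[, 1]; ev <- q[, 2] - p[, 2]
  wu <- p[, 1] - C[1]; wv <- p[, 2] - C[2]

  ## rays x edges, all at once: t = cross(w, e) / cross(d, e),
  ##                            s = cross(w, d) / cross(d, e)
  cde <- outer(dir_u, ev) - outer(dir_v, eu)        # n_rays x n_edges
  cwe <- matrix(wu * ev - wv * eu, nrow = n_samples,
                ncol = nrow(p), byrow = TRUE)
  t <- cwe / cde
  s <- (outer(dir_v, wu) - outer(dir_u, wv)) / cde
  valid <- is.finite(t) & t > 1e-9 & s >= 0 & s < 1
  t[!valid] <- -Inf
  radii <- apply(t, 1, max)
  if (any(!is.finite(radii)))
    cranio_abort("cranio_center_outside",
                 "a ray found no boundary intersection; outline is degenerate")
  ## multiple genuinely distinct crossings mean the outline is not
  ## star-shaped from the centroid (a ray grazing a vertex produces two
  ## nearly identical hits and does not count)
  ncross <- rowSums(valid & t < radii - 1e-6) + 1L
  if (any(ncross > 1))
    warning(sprintf(
      "outline is not star-shaped from its centroid: %d of %d rays cross the boundary more than once; outermost intersections used",
      sum(ncross > 1), n_samples), call. = FALSE)
  attr(radii, "theta_deg") <- theta
  radii
}

#' Normalize absolute radii to a relative polar curve
#'
#' Divides by the arithmetic mean radius, so a value of 1.0 is the mean and
#' values below/above 1.0 are below/above the mean - making the curve
#' independent of skull size (and hence age).
#'
#' @param radii_abs numeric vector of positive radii in mm (one per degree).
#' @param frame the `cranio_frame` the radii were sampled in (optional,
#'   carried along for provenance).
#' @return a `cranio_curve`: list with `theta_deg`, `radii_rel`,
#'   `radii_abs`, `mean_radius`, `frame`.
#' @export
normalize_curve <- function(radii_abs, frame = NULL) {
  radii_abs <- as.numeric(radii_abs)
  if (any(!is.finite(radii_abs)) || any(radii_abs <= 0))
    cranio_abort("cranio_invalid_radius", "all radii must be positive and finite")
  m <- mean(radii_abs)
  structure(list(
    theta_deg = seq_along(radii_abs) - 1,
    radii_rel = radii_abs / m,
    radii_abs = radii_abs,
    mean_radius = m,
    frame = frame
  ), class = "cranio_curve")
}

#' @export
print.cranio_curve <- function(x, ...) {
  cat(sprintf(
    "cranio_curve: %d samples, mean radius %.2f mm, rel range [%.3f, %.3f]\n",
    length(x$radii_rel), x$mean_radius, min(x$radii_rel), max(x$radii_rel)))
  invisible(x)
}

#' Extract the full polar curve from an outline
#'
#' Convenience wrapper: [polar_sample()] then [normalize_curve()].
#'
#' @inheritParams polar_sample
#' @return a `cranio_curve`.
#' @export
outline_to_curve <- function(outline, frame, n_samples = 360) {
  normalize_curve(polar_sample(outline, frame, n_samples), frame = frame)
}

#' Read / write curve CSV
#'
#' Columns `theta_deg` (0-359), `radius_rel`, `radius_mm`. The curve CSV is
#' the inter-stage contract: outlines from other modalities can enter the
#' feature pipeline through it without a mesh.
#'
#' @param path CSV path.
#' @return `read_curve_csv`: a `cranio_curve` (no frame attached).
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path))
    cranio_abort("cranio_input_error", paste("curve file not found:", path))
  df <- utils::read.csv(path)
  need <- c("theta_deg", "radius_rel", "radius_mm")
  if (!all(need %in% names(df)))
    cranio_abort("cranio_input_error",
                 "curve CSV needs columns theta_deg,radius_rel,radius_mm")
  df <- df[order(df$theta_deg), ]
  normalize_curve(df$radius_mm)
}

#' @rdname read_curve_csv
#' @param curve a `cranio_curve` to write.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(
    theta_deg = curve$theta_deg,
    radius_rel = sprintf("%.15g", curve$radii_rel),
    radius_mm = sprintf("%.15g", curve$radii_abs)
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a polar curve
#'
#' Relative radius against angle, x-axis 0-360 degrees: the occiput at 0 and
#' 360, the right side near 90, the forehead near 180, the left side near
#' 270. The mean level 1.0 is drawn as a reference line.
#'
#' @param x a `cranio_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cranio_curve <- function(x, ...) {
  graphics::plot(x$theta_deg, x$radii_rel, type = "l",
                 xlab = "angle from occipital start [deg]",
                 ylab = "relative radius", xlim = c(0, 360),
                 xaxs = "i", ...)
  graphics::abline(h = 1, lty = 3, col = "grey40")
  graphics::axis(1, at = seq(0, 360, 90))
  invisible(x)
}

#' Write a curve plot to PNG
#'
#' @param curve a `cranio_curve`.
#' @param path output .png path.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
write_curve_plot <- function(curve, path, title = "skull outline polar curve") {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  plot(curve, main = title)
  invisible(path)
}
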