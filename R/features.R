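## Curve feature extraction: the named extrema (forehead F, occiput O,
## right/left troughs R and L, with angular positions XF, XR, XL), the
## F-0.1 forehead-width crossings (XFR, XFL), all derived length/width and
## asymmetry indices, the 180 +/- 12 degree forehead-centering rule, and
## the phenotype classifier built on them.

#' Feature-extraction configuration
#'
#' Windows and thresholds for curve feature extraction and classification.
#' The forehead-peak search window (90-270 deg) and the occiput window
#' (+/- 45 deg around 0) enforce the expected peak/trough ordering of the
#' curve; the classifier thresholds are heuristics derived from the
#' per-phenotype feature regimes of small clinical groups (n = 5 each) and
#' are meant to be overridden as larger references become available.
#'
#' @param peak_window half-width in degrees of the forehead-centering rule
#'   (default 12; 3.5\% of 360 deg rounds to 12.6, matching the asymmetry
#'   cutoff used for the cranial vault asymmetry index).
#' @param forehead_window angular window (deg) searched for the forehead
#'   peak.
#' @param occiput_halfwidth half-width (deg) of the occiput window around 0.
#' @param drop relative-radius drop below the forehead peak defining the
#'   forehead-width crossings (default 0.1).
#' @param strict_table1 if `TRUE`, the occiput/forehead-vs-sides differences
#'   use `R/2 - L/2` (the printed formula variant) instead of the mean of
#'   sides `R/2 + L/2`.
#' @param t_scapho length/width ratio at or above which scaphocephaly is
#'   called (default 1.40).
#' @param t_trigono forehead width below which trigonocephaly is considered
#'   (default 66).
#' @param t_brachy forehead width above which brachycephaly is considered
#'   (default 110).
#' @param asym_window asymmetry-ratio interval treated as compatible with a
#'   centered (non-plagiocephalic) forehead.
#' @param brachy_fo_tol |F - O| tolerance for the brachycephaly rule.
#' @return a list of class `cranio_config`.
#' @export
cranio_config <- function(peak_window = 12,
                          forehead_window = c(90, 270),
                          occiput_halfwidth = 45,
                          drop = 0.1,
                          strict_table1 = FALSE,
                          t_scapho = 1.40,
                          t_trigono = 66,
                          t_brachy = 110,
                          asym_window = c(0.7, 1.6),
                          brachy_fo_tol = 0.03) {
  structure(list(peak_window = peak_window,
                 forehead_window = forehead_window,
                 occiput_halfwidth = occiput_halfwidth,
                 drop = drop,
                 strict_table1 = strict_table1,
                 t_scapho = t_scapho, t_trigono = t_trigono,
                 t_brachy = t_brachy, asym_window = asym_window,
                 brachy_fo_tol = brachy_fo_tol),
            class = "cranio_config")
}

## tie-break helper: among candidate indices with equal value, the one whose
## angle is nearest `target` (circular distance), then the smaller angle
.pick_tie <- function(theta, value, best, target) {
  cand <- which(abs(value - best) < 1e-12)
  d <- abs(theta[cand] - target)
  d <- pmin(d, 360 - d)
  cand[order(d, theta[cand])][1]
}

#' Extract the named curve extrema
#'
#' Finds the forehead peak `F` (maximum relative radius in the forehead
#' window, position `XF`), the right and left troughs `R`/`L` (minima over
#' (0, XF) and (XF, 360), positions `XR`/`XL`) and the occiput peak `O`
#' (maximum within the window around 0 deg). Ties are broken toward 180
#' (forehead), 90 (right), 270 (left) and 0 (occiput).
#'
#' @param curve a `cranio_curve` with 360 one-degree samples.
#' @param config a [cranio_config()].
#' @return list with elements `F`, `O`, `R`, `L` (relative radii) and `XF`,
#'   `XR`, `XL`, `XO` (degrees).
#' @export
extract_extrema <- function(curve, config = cranio_config()) {
  r <- curve$radii_rel
  th <- curve$theta_deg
  if (length(r) != 360)
    cranio_abort("cranio_input_error", "extrema extraction expects 360 one-degree samples")
  if (max(r) - min(r) < 1e-6)
    cranio_abort("cranio_flat_curve", "curve is flat; no extrema to extract")

  fw <- config$forehead_window
  idx_f <- which(th >= fw[1] & th <= fw[2])
  i <- .pick_tie(th[idx_f], r[idx_f], max(r[idx_f]), 180)
  XF <- th[idx_f][i]; Fv <- r[idx_f][i]

  idx_r <- which(th > 0 & th < XF)
  if (!length(idx_r))
    cranio_abort("cranio_flat_curve", "no samples between start and forehead peak")
  i <- .pick_tie(th[idx_r], r[idx_r], min(r[idx_r]), 90)
  XR <- th[idx_r][i]; Rv <- r[idx_r][i]

  idx_l <- which(th > XF & th < 360)
  i <- .pick_tie(th[idx_l], r[idx_l], min(r[idx_l]), 270)
  XL <- th[idx_l][i]; Lv <- r[idx_l][i]

  oh <- config$occiput_halfwidth
  idx_o <- which(th >= 360 - oh | th <= oh)
  i <- .pick_tie(th[idx_o], r[idx_o], max(r[idx_o]), 0)
  XO <- th[idx_o][i]; Ov <- r[idx_o][i]

  list(F = Fv, O = Ov, R = Rv, L = Lv, XF = XF, XR = XR, XL = XL, XO = XO)
}

#' Derived length/width calculations from the four extrema
#'
#' All derived indices: mean of sides `R/2 + L/2`, total maximum length
#' `F + O`, occiput/forehead differences to the sides, total minimum width
#' `R + L`, the width/length ratio (comparable with the cephalic index) and
#' its reciprocal, and the forehead-occiput difference `F - O`.
#'
#' @param F,O,R,L relative radii (all > 0).
#' @param strict_table1 use the `R/2 - L/2` printed variant for the two
#'   difference formulas (see [cranio_config()]).
#' @return named list of the nine derived quantities.
#' @export
table1_calculations <- function(F, O, R, L, strict_table1 = FALSE) {
  if (any(c(F, O, R, L) <= 0))
    cranio_abort("cranio_invalid_radius", "extrema must be positive")
  sides <- if (strict_table1) R / 2 - L / 2 else R / 2 + L / 2
  list(
    mean_sides = R / 2 + L / 2,
    total_max_length = F + O,
    diff_occiput_sides = O - sides,
    diff_forehead_sides = F - sides,
    total_min_width = R + L,
    width_length_ratio = (R + L) / (F + O),
    diff_forehead_occiput = F - O,
    length_width_ratio = (F + O) / (R + L)
  )
}

#' Forehead width at the F - 0.1 level
#'
#' Walks outward from the forehead peak to the nearest crossings of the
#' level `F - drop` on each side (`XFR` below `XF`, `XFL` above), with
#' linear interpolation between integer degrees, and returns the forehead
#' width `(XFL - XFR) / (F - drop)`. A broad flat forehead yields a large
#' value; a pointed (keel-shaped) forehead a small one.
#'
#' @param curve a `cranio_curve`.
#' @param F,XF forehead peak value and position from [extract_extrema()].
#' @param drop the level drop below the peak (default 0.1, in relative
#'   radius units).
#' @return list with `XFR`, `XFL` (fractional degrees) and `forehead_width`.
#' @export
forehead_width <- function(curve, F, XF, drop = 0.1) {
  r <- curve$radii_rel
  target <- F - drop
  ## right side: largest theta < XF where the curve crosses the level
  XFR <- NA_real_
  for (th in seq(XF - 1, 0)) {
    if (r[th + 1] < target) {
      XFR <- th + (target - r[th + 1]) / (r[th + 2] - r[th + 1])
      break
    }
  }
  ## left side: smallest theta > XF with a crossing
  XFL <- NA_real_
  for (th in seq(XF + 1, 359)) {
    if (r[th + 1] < target) {
      XFL <- (th - 1) + (r[th] - target) / (r[th] - r[th + 1])
      break
    }
  }
  if (is.na(XFR) || is.na(XFL))
    cranio_abort("cranio_peak_too_flat",
                 sprintf("curve never drops below F - %.2g on one side of the forehead peak", drop))
  list(XFR = XFR, XFL = XFL, forehead_width = (XFL - XFR) / target)
}

#' Is the forehead peak centered?
#'
#' `TRUE` iff `XF` lies within 180 +/- `window` degrees (boundaries
#' inclusive). The default 12-degree window corresponds to the 3.5\%
#' asymmetry cutoff: 3.5\% of 360 deg = 12.6.
#'
#' @param XF forehead peak angle in degrees.
#' @param window half-width in degrees (default 12).
#' @return logical.
#' @export
peak_centered <- function(XF, window = 12) {
  XF >= 180 - window & XF <= 180 + window
}

#' Extract all curve features
#'
#' Runs [extract_extrema()], [table1_calculations()], [forehead_width()]
#' and [peak_centered()] on a curve and assembles the full feature set.
#'
#' @param curve a `cranio_curve` (360 one-degree samples).
#' @param config a [cranio_config()].
#' @return an object of class `cranio_features`: named list with `F`, `O`,
#'   `R`, `L`, `XF`, `XR`, `XL`, `XFR`, `XFL`, the derived calculations,
#'   `asymmetry_ratio` and `peak_centered`.
#' @export
curve_features <- function(curve, config = cranio_config()) {
  ex <- extract_extrema(curve, config)
  calc <- table1_calculations(ex$F, ex$O, ex$R, ex$L,
                              strict_table1 = config$strict_table1)
  fwid <- forehead_width(curve, ex$F, ex$XF, drop = config$drop)
  feats <- c(
    ex[c("F", "O", "R", "L", "XF", "XR", "XL")],
    list(XFR = fwid$XFR, XFL = fwid$XFL),
    calc,
    list(forehead_width = fwid$forehead_width,
         asymmetry_ratio = (ex$XF - ex$XR) / (ex$XL - ex$XF),
         peak_centered = peak_centered(ex$XF, config$peak_window))
  )
  structure(feats, class = "cranio_features")
}

#' @export
print.cranio_features <- function(x, ...) {
  cat("cranio_features:\n")
  cat(sprintf("  F=%.3f (XF=%g) O=%.3f R=%.3f (XR=%g) L=%.3f (XL=%g)\n",
              x$F, x$XF, x$O, x$R, x$XR, x$L, x$XL))
  cat(sprintf("  length/width=%.3f  forehead width=%.2f  asymmetry=%.3f  peak centered: %s\n",
              x$length_width_ratio, x$forehead_width, x$asymmetry_ratio,
              x$peak_centered))
  invisible(x)
}

#' Features as a one-row data frame
#'
#' @param x a `cranio_features`.
#' @param ... unused.
#' @return one-row `data.frame` with the feature names as columns.
#' @export
as.data.frame.cranio_features <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Write features to CSV or JSON
#'
#' @param features a `cranio_features` or a data frame of feature rows.
#' @param path output path ending in .csv or .json.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- if (inherits(features, "cranio_features")) as.data.frame(features)
        else as.data.frame(features)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") utils::write.csv(df, path, row.names = FALSE)
  else if (ext == "json") jsonlite::write_json(df, path, auto_unbox = FALSE,
                                               digits = NA)
  else cranio_abort("cranio_input_error",
                    paste("unsupported features format:", ext))
  invisible(path)
}

#' Classify the phenotype from curve features
#'
#' Ordered decision rules over the feature set:
#' \enumerate{
#'   \item forehead peak shifted beyond 180 +/- 12 deg: toward the right
#'     side of the head (`XF < 168`) = right-sided anterior plagiocephaly;
#'     toward the left (`XF > 192`) = left-sided;
#'   \item `length_width_ratio >= t_scapho` = scaphocephaly (long narrow
#'     skull);
#'   \item narrow pointed forehead (`forehead_width < t_trigono`) with a
#'     centered peak or near-symmetric asymmetry ratio = trigonocephaly;
#'   \item broad flat forehead (`forehead_width > t_brachy`) with forehead
#'     and occiput of near-equal height = brachycephaly;
#'   \item otherwise control.
#' }
#' Thresholds are configurable via [cranio_config()].
#'
#' @param features a `cranio_features`.
#' @param config a [cranio_config()].
#' @return an object of class `cranio_phenotype`: list with `label` (one of
#'   control, scaphocephaly, trigonocephaly, brachycephaly,
#'   plagio_anterior_right, plagio_anterior_left) and `rules`, the per-rule
#'   evaluation trace.
#' @export
classify <- function(features, config = cranio_config()) {
  w <- config$peak_window
  rules <- list(
    plagio_right = features$XF < 180 - w,
    plagio_left = features$XF > 180 + w,
    scapho = features$length_width_ratio >= config$t_scapho,
    trigono = features$forehead_width < config$t_trigono &&
      (features$peak_centered ||
         (features$asymmetry_ratio >= config$asym_window[1] &&
          features$asymmetry_ratio <= config$asym_window[2])),
    brachy = features$forehead_width > config$t_brachy &&
      abs(features$diff_forehead_occiput) <= config$brachy_fo_tol
  )
  label <- if (rules$plagio_right) "plagio_anterior_right"
    else if (rules$plagio_left) "plagio_anterior_left"
    else if (rules$scapho) "scaphocephaly"
    else if (rules$trigono) "trigonocephaly"
    else if (rules$brachy) "brachycephaly"
    else "control"
  structure(list(label = label, rules = rules), class = "cranio_phenotype")
}

#' @export
print.cranio_phenotype <- function(x, ...) {
  cat(sprintf("cranio_phenotype: %s\n", x$label))
  cat("  rules fired:",
      paste(names(x$rules)[unlist(x$rules)], collapse = ", "), "\n")
  invisible(x)
}
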