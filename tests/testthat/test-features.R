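test_that("extrema of a closed-form curve match dense evaluation of the formula", {
  f <- function(th) 1 + 0.2 * cos(2 * th * pi / 180) - 0.05 * cos(th * pi / 180)
  cv <- toy_curve(f)
  ex <- extract_extrema(cv)
  # oracle: evaluate the closed form on the integer-degree grid directly
  th <- 0:359; r <- f(th) / mean(f(th))
  win_f <- th[th >= 90 & th <= 270]
  expect_equal(ex$XF, win_f[which.max(r[th %in% win_f])])
  expect_equal(ex$XF, 180)  # analytic maximum of the form
  win_r <- th[th > 0 & th < ex$XF]
  expect_equal(ex$XR, win_r[which.min(r[win_r + 1])])
  win_l <- th[th > ex$XF]
  expect_equal(ex$XL, win_l[which.min(r[win_l + 1])])
  expect_equal(ex$F, max(r[91:271]), tolerance = 1e-12)
  expect_equal(ex$O, r[1], tolerance = 1e-12)  # occipital peak at theta = 0
})

test_that("symmetric curves give a centered peak, equal troughs, unit asymmetry", {
  cv <- toy_curve(function(th) 1 + 0.15 * cos(2 * th * pi / 180))
  fe <- curve_features(cv)
  expect_equal(fe$XF, 180)
  expect_equal(fe$R, fe$L, tolerance = 1e-12)
  expect_equal(fe$XF - fe$XR, fe$XL - fe$XF)
  expect_equal(fe$asymmetry_ratio, 1, tolerance = 1e-12)
  expect_true(fe$peak_centered)
})

test_that("a flat curve cannot be analyzed", {
  expect_error(extract_extrema(normalize_curve(rep(5, 360))),
               class = "cranio_flat_curve")
})

test_that("extrema ties break toward the canonical angles", {
  # plateau of equal maxima around the forehead window
  r <- rep(1, 360); r[151:211] <- 1.2; r[46] <- 0.8; r[316] <- 0.8
  ex <- extract_extrema(normalize_curve(r))
  expect_equal(ex$XF, 180)
})

test_that("derived calculations reproduce the published group arithmetic", {
  # scaphocephaly group means: long occiput, narrow sides
  sc <- table1_calculations(F = 1.16, O = 1.24, R = 0.81, L = 0.81)
  expect_equal(sc$diff_forehead_occiput, -0.08)
  expect_equal(sc$diff_occiput_sides, 0.43)
  expect_equal(sc$mean_sides, 0.81)
  # trigonocephaly: prominent forehead
  tr <- table1_calculations(F = 1.18, O = 1.09, R = 0.89, L = 0.89)
  expect_equal(tr$diff_forehead_occiput, 0.09)
  expect_equal(tr$diff_occiput_sides, 0.20)
  # unit curve: all differences zero, both ratios one
  un <- table1_calculations(1, 1, 1, 1)
  expect_equal(un$diff_forehead_occiput, 0)
  expect_equal(un$diff_occiput_sides, 0)
  expect_equal(un$width_length_ratio, 1)
  expect_equal(un$length_width_ratio, 1)
})

test_that("the two ratio forms are reciprocal", {
  ca <- table1_calculations(F = 1.13, O = 1.19, R = 0.84, L = 0.88)
  expect_equal(ca$width_length_ratio * ca$length_width_ratio, 1, tolerance = 1e-9)
})

test_that("the strict printed-formula variant uses R/2 - L/2", {
  st <- table1_calculations(F = 1.16, O = 1.24, R = 0.81, L = 0.85,
                            strict_table1 = TRUE)
  expect_equal(st$diff_occiput_sides, 1.24 - (0.81 / 2 - 0.85 / 2))
  expect_equal(st$diff_forehead_sides, 1.16 - (0.81 / 2 - 0.85 / 2))
  # mean_sides itself is always the mean
  expect_equal(st$mean_sides, 0.83)
})

test_that("forehead width interpolates the F - 0.1 crossings", {
  # triangular peak on a low baseline: crossings at exactly 175 and 185
  Fv <- 1.3
  r <- pmax(Fv - abs(0:359 - 180) / 50, 0.9)
  cv <- structure(list(theta_deg = 0:359, radii_rel = r,
                       radii_abs = r * 80, mean_radius = 80, frame = NULL),
                  class = "cranio_curve")
  fw <- forehead_width(cv, F = Fv, XF = 180)
  expect_equal(fw$XFR, 175, tolerance = 1e-9)
  expect_equal(fw$XFL, 185, tolerance = 1e-9)
  expect_equal(fw$forehead_width, 10 / (Fv - 0.1), tolerance = 1e-9)
  # a pointed forehead is narrower than a broad one at equal peak height
  r2 <- pmax(Fv - abs(0:359 - 180) / 20, 0.9)
  cv2 <- cv; cv2$radii_rel <- r2
  expect_lt(forehead_width(cv2, Fv, 180)$forehead_width, fw$forehead_width)
  # symmetric curve: crossings equidistant from the peak
  expect_equal(fw$XFL - 180, 180 - fw$XFR, tolerance = 1e-9)
})

test_that("a peak that never drops by 0.1 raises peak-too-flat", {
  r <- 1 + 0.04 * cos(2 * (0:359) * pi / 180)
  expect_error(forehead_width(normalize_curve(r), F = max(r), XF = 180),
               class = "cranio_peak_too_flat")
})

test_that("the 180 +/- 12 degree rule is boundary inclusive", {
  expect_true(peak_centered(180))
  expect_false(peak_centered(167))
  expect_true(peak_centered(168))
  expect_true(peak_centered(192))
  expect_false(peak_centered(193))
})

test_that("classification follows the ordered rules", {
  base <- list(F = 1.13, O = 1.13, R = 0.87, L = 0.87, XF = 180, XR = 90,
               XL = 270, XFR = 140, XFL = 220, mean_sides = 0.87,
               total_max_length = 2.26, diff_occiput_sides = 0.26,
               diff_forehead_sides = 0.26, total_min_width = 1.74,
               width_length_ratio = 0.77, diff_forehead_occiput = 0,
               length_width_ratio = 1.3, forehead_width = 78,
               asymmetry_ratio = 1, peak_centered = TRUE)
  mk <- function(...) {
    f <- utils::modifyList(base, list(...))
    structure(f, class = "cranio_features")
  }
  expect_equal(classify(mk())$label, "control")
  expect_equal(classify(mk(XF = 160))$label, "plagio_anterior_right")
  expect_equal(classify(mk(XF = 200))$label, "plagio_anterior_left")
  expect_equal(classify(mk(length_width_ratio = 1.485))$label, "scaphocephaly")
  expect_equal(classify(mk(forehead_width = 48))$label, "trigonocephaly")
  expect_equal(classify(mk(forehead_width = 123))$label, "brachycephaly")
  # the peak-shift rule outranks the others
  expect_equal(classify(mk(XF = 160, length_width_ratio = 1.5))$label,
               "plagio_anterior_right")
  # brachycephaly requires forehead and occiput of near-equal height
  expect_equal(classify(mk(forehead_width = 123,
                           diff_forehead_occiput = 0.08))$label, "control")
})
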