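test_that("ICC(2,1) matches the direct variance-components oracle", {
  set.seed(11)
  # fixed 6 x 3 table with target, rater and residual components
  x <- outer(rnorm(6, 0, 2), rep(1, 3)) + outer(rep(1, 6), c(-0.3, 0.1, 0.4)) +
    matrix(rnorm(18, 0, 0.5), 6, 3)
  expect_equal(icc_2_1(x), icc_oracle(x), tolerance = 1e-9)
  # a second regime: strong rater effect
  y <- outer(rnorm(8, 0, 1), rep(1, 4)) + outer(rep(1, 8), c(0, 2, 4, 6)) +
    matrix(rnorm(32, 0, 0.3), 8, 4)
  expect_equal(icc_2_1(y), icc_oracle(y), tolerance = 1e-9)
})

test_that("ICC(2,1) is 1 under perfect agreement and ~0 under pure noise", {
  x <- outer(c(3, 7, 1, 9, 5), rep(1, 3))  # raters identical, targets differ
  expect_equal(icc_2_1(x), 1)
  set.seed(42)
  z <- matrix(rnorm(3000), 1000, 3)        # no target effect at all
  expect_lt(abs(icc_2_1(z)), 0.05)
  expect_error(icc_2_1(matrix(2, 4, 3)), class = "cranio_undefined_icc")
})

test_that("ICC(2,1) is invariant to shift and positive rescaling", {
  set.seed(5)
  x <- outer(rnorm(7), rep(1, 3)) + matrix(rnorm(21, 0, 0.4), 7, 3)
  expect_equal(icc_2_1(x + 100), icc_2_1(x), tolerance = 1e-9)
  expect_equal(icc_2_1(x * 3.5), icc_2_1(x), tolerance = 1e-9)
})

test_that("a systematic rater offset lowers absolute agreement below consistency", {
  set.seed(8)
  truth <- rnorm(26, 0, 10)
  x <- cbind(truth + rnorm(26, 0, 0.5), truth + rnorm(26, 0, 0.5) + 50)
  icc_abs <- icc_2_1(x)
  # consistency-style coefficient (rater effect excluded) as the comparator
  n <- nrow(x); k <- ncol(x); m <- mean(x)
  msr <- k * sum((rowMeans(x) - m)^2) / (n - 1)
  mse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + m)^2) / ((n - 1) * (k - 1))
  icc_cons <- (msr - mse) / (msr + (k - 1) * mse)
  expect_lt(icc_abs, icc_cons)
  expect_gt(icc_cons, 0.99)
})

test_that("reliability report flags jittered raters as acceptable", {
  set.seed(3)
  truth <- data.frame(subject = 1:26,
                      x = rnorm(26, 0, 20), y = rnorm(26, 0, 20),
                      z = rnorm(26, 0, 20))
  rows <- expand.grid(subject = 1:26, rater = c("A", "B", "C"), session = 1:3)
  ratings <- data.frame(rows, landmark = "ex_left")
  idx <- match(ratings$subject, truth$subject)
  ratings$x <- truth$x[idx] + rnorm(nrow(ratings), 0, 0.1)
  ratings$y <- truth$y[idx] + rnorm(nrow(ratings), 0, 0.1)
  ratings$z <- truth$z[idx] + rnorm(nrow(ratings), 0, 0.1)
  rep <- reliability_report(ratings)
  xyz <- rep[rep$axis %in% c("x", "y", "z"), ]
  expect_true(all(xyz$icc > 0.99))
  expect_true(all(xyz$acceptable))
  expect_setequal(unique(rep$scope), c("intra", "inter"))
})

test_that("a duplicated rater yields inter-rater ICC of exactly 1", {
  d1 <- data.frame(subject = rep(1:6, 2), landmark = "po_left",
                   rater = rep(c("A", "B"), each = 6), session = 1,
                   x = rep(c(1, 5, 3, 8, 2, 9), 2),
                   y = rep(c(2, 1, 7, 4, 6, 3), 2),
                   z = rep(c(9, 2, 5, 1, 8, 4), 2))
  rep <- reliability_report(rbind(d1, within(d1, session <- 2)))
  inter <- rep[rep$scope == "inter" & rep$axis == "x", ]
  expect_equal(inter$icc, 1)
})

test_that("group curve summaries report per-degree range correctly", {
  base <- normalize_curve(80 + 8 * cos(2 * (0:359) * pi / 180))
  # plain numeric vectors are accepted alongside curve objects
  gc <- group_mean_curves(list(base, base, base, base$radii_rel,
                               base$radii_rel + 0.1),
                          c("a", "a", "a", "b", "b"))
  expect_equal(gc$a$range_mean, 0)
  expect_equal(gc$a$range_sd, 0)
  expect_equal(gc$b$range_mean, 0.1, tolerance = 1e-9)
  expect_equal(gc$b$range_sd, 0, tolerance = 1e-9)
  expect_error(group_mean_curves(list(base, base, base), c("a", "a", "b")),
               class = "cranio_singleton_group")
})

test_that("Games-Howell with two groups reduces to Welch's t-test", {
  set.seed(21)
  x <- c(rnorm(12, 0, 1), rnorm(17, 0.8, 2.5))
  g <- factor(rep(c("a", "b"), c(12, 17)))
  gh <- games_howell(x, g)
  wt <- t.test(x[g == "a"], x[g == "b"], var.equal = FALSE)
  expect_equal(gh$p, wt$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-9)
  expect_equal(abs(gh$t), abs(unname(wt$statistic)), tolerance = 1e-12)
})

test_that("Games-Howell p-values are monotone in the mean difference", {
  set.seed(31)
  noise <- rnorm(60)
  ps <- vapply(c(0.2, 0.6, 1.2, 2.4), function(d) {
    x <- noise + rep(c(0, d, 0), each = 20)
    gh <- games_howell(x, factor(rep(c("a", "b", "c"), each = 20)))
    gh$p[gh$group1 == "a" & gh$group2 == "b"]
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("compare_groups reports ANOVA, Levene and adjusted pairwise results", {
  set.seed(13)
  x <- c(rnorm(25, 0, 1), rnorm(25, 0, 1), rnorm(25, 3, 4))
  g <- factor(rep(c("a", "b", "c"), each = 25))
  cmp <- compare_groups(x, g)
  # oracle: base R equal-variance ANOVA and mean-centered Levene via lm
  an <- oneway.test(x ~ g, var.equal = TRUE)
  expect_equal(cmp$anova$F, unname(an$statistic), tolerance = 1e-12)
  expect_equal(cmp$anova$p, an$p.value, tolerance = 1e-12)
  z <- abs(x - ave(x, g))
  lv <- anova(lm(z ~ g))
  expect_equal(cmp$levene$W, lv$`F value`[1], tolerance = 1e-9)
  expect_equal(cmp$levene$p, lv$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(cmp$pairwise$p_bonferroni,
               pmin(1, cmp$pairwise$p * nrow(cmp$pairwise)))
  expect_error(compare_groups(x[1:25], g[1:25]),
               class = "cranio_singleton_group")
  expect_error(compare_groups(c(1, 1, 2, 2), factor(c("a", "a", "b", "b"))),
               class = "cranio_degenerate_variance")
})

test_that("a separated group is flagged and a null pair is not, across replicates", {
  set.seed(77)
  n <- 15; reps <- 300
  hit_sep <- hit_null <- 0
  for (r in seq_len(reps)) {
    se <- sqrt(2 / n)  # standard error of a two-group mean difference
    x <- c(rnorm(n, 0), rnorm(n, 0), rnorm(n, 5 * se))
    g <- factor(rep(c("a", "b", "c"), each = n))
    gh <- games_howell(x, g)
    gh$sig <- pmin(1, gh$p * 3) < 0.05
    if (gh$sig[gh$group1 == "a" & gh$group2 == "c"]) hit_sep <- hit_sep + 1
    if (gh$sig[gh$group1 == "a" & gh$group2 == "b"]) hit_null <- hit_null + 1
  }
  expect_gt(hit_sep / reps, 0.95)
  expect_lt(hit_null / reps, 0.05)
})
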