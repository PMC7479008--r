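## Reliability and group-comparison statistics: ICC(2,1) (two-way random
## effects, absolute agreement, single measures) for landmark repeatability,
## per-degree group curve summaries, and the omnibus/post hoc chain
## (one-way ANOVA, Levene's test, Games-Howell with Bonferroni correction).

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Computed from the two-way ANOVA mean squares of an `n x k` table (rows =
#' targets, columns = raters or sessions):
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' where MSR is the between-target, MSC the between-rater and MSE the
#' residual mean square. Absolute agreement: a systematic offset between
#' raters lowers the coefficient.
#'
#' @param table numeric matrix, `n >= 2` targets by `k >= 2` raters, no
#'   missing cells.
#' @return the ICC estimate (a single number in \[-1, 1\] for well-posed
#'   tables).
#' @export
icc_2_1 <- function(table) {
  x <- as.matrix(table)
  if (any(!is.finite(x)))
    cranio_abort("cranio_input_error", "ratings table has missing or non-finite cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    cranio_abort("cranio_input_error", "ratings table needs >= 2 targets and >= 2 raters")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x))) * 10)
    cranio_abort("cranio_undefined_icc", "zero total variance; ICC undefined")
  m <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  resid <- x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300)
    cranio_abort("cranio_undefined_icc", "degenerate ANOVA decomposition")
  (msr - mse) / denom
}

#' Landmark reliability report
#'
#' Intra-rater ICCs (sessions as repeated measures, per rater) and
#' inter-rater ICCs (raters as columns, per-rater session means) for each
#' landmark, computed per coordinate axis and on the 3-D Euclidean deviation
#' of each rating from the per-subject/landmark mean point. ICC(2,1) with
#' the acceptability cutoff 0.75 throughout.
#'
#' @param ratings long-format data frame with columns `subject`, `landmark`,
#'   `rater`, `session`, `x`, `y`, `z` (coordinates in mm).
#' @return data frame with columns `scope` (intra/inter), `rater` (`NA` for
#'   inter), `landmark`, `axis` (x, y, z, r3d), `icc`, `acceptable`; an axis
#'   with no variance at all (ICC undefined) is reported as `NA`.
#' @export
reliability_report <- function(ratings) {
  need <- c("subject", "landmark", "rater", "session", "x", "y", "z")
  if (!all(need %in% names(ratings)))
    cranio_abort("cranio_input_error",
                 paste("ratings need columns:", paste(need, collapse = ",")))
  ratings <- as.data.frame(ratings)
  ## Euclidean deviation from the per-(subject, landmark) mean point
  key <- interaction(ratings$subject, ratings$landmark, drop = TRUE)
  mx <- stats::ave(ratings$x, key); my <- stats::ave(ratings$y, key)
  mz <- stats::ave(ratings$z, key)
  ratings$r3d <- sqrt((ratings$x - mx)^2 + (ratings$y - my)^2 + (ratings$z - mz)^2)

  axes <- c("x", "y", "z", "r3d")
  icc_or_na <- function(m)
    tryCatch(icc_2_1(m), cranio_undefined_icc = function(e) NA_real_)
  out <- list()
  for (lm in unique(ratings$landmark)) {
    d <- ratings[ratings$landmark == lm, ]
    ## intra-rater: subjects x sessions, per rater
    for (rt in unique(d$rater)) {
      dr <- d[d$rater == rt, ]
      dr <- dr[order(dr$subject, dr$session), ]
      for (ax in axes) {
        m <- matrix(dr[[ax]], nrow = length(unique(dr$subject)), byrow = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          scope = "intra", rater = as.character(rt), landmark = lm, axis = ax,
          icc = icc_or_na(m), stringsAsFactors = FALSE)
      }
    }
    ## inter-rater: subjects x raters, averaging sessions within rater
    agg <- stats::aggregate(d[axes], by = list(subject = d$subject,
                                               rater = d$rater), FUN = mean)
    agg <- agg[order(agg$rater, agg$subject), ]
    nsub <- length(unique(agg$subject))
    for (ax in axes) {
      m <- matrix(agg[[ax]], nrow = nsub)
      out[[length(out) + 1L]] <- data.frame(
        scope = "inter", rater = NA_character_, landmark = lm, axis = ax,
        icc = icc_or_na(m), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$acceptable <- res$icc > 0.75
  res
}

#' Per-degree group curve summaries
#'
#' For each group: the per-degree mean curve, the per-degree range (maximum
#' minus minimum relative radius across group members), and the mean and SD
#' of that range over the 360 degrees. A wide normal variation shows up as a
#' large mean range; growth-restricted synostotic groups show smaller ones.
#'
#' @param curves list of `cranio_curve` objects (all 360 samples).
#' @param groups factor or character vector of group labels, one per curve.
#' @return list of class `cranio_group_curves`, one element per group with
#'   `n`, `mean_curve`, `range`, `range_mean`, `range_sd`.
#' @export
group_mean_curves <- function(curves, groups) {
  groups <- as.factor(groups)
  if (length(curves) != length(groups))
    cranio_abort("cranio_input_error", "one group label per curve required")
  mat <- vapply(curves, function(cv) {
    r <- if (inherits(cv, "cranio_curve")) cv$radii_rel else as.numeric(cv)
    if (length(r) != 360)
      cranio_abort("cranio_input_error", "all curves must have 360 samples")
    r
  }, numeric(360))
  out <- lapply(levels(groups), function(g) {
    sub <- mat[, groups == g, drop = FALSE]
    if (ncol(sub) < 2)
      cranio_abort("cranio_singleton_group",
                   paste0("group '", g, "' has fewer than 2 curves"))
    rng <- apply(sub, 1, max) - apply(sub, 1, min)
    list(n = ncol(sub), mean_curve = rowMeans(sub), range = rng,
         range_mean = mean(rng), range_sd = stats::sd(rng))
  })
  names(out) <- levels(groups)
  structure(out, class = "cranio_group_curves")
}

#' @export
print.cranio_group_curves <- function(x, ...) {
  cat("cranio_group_curves (per-degree range of relative radius):\n")
  for (g in names(x))
    cat(sprintf("  %-22s n=%d  mean range %.3f (SD %.3f)\n",
                g, x[[g]]$n, x[[g]]$range_mean, x[[g]]$range_sd))
  invisible(x)
}

#' Games-Howell pairwise comparisons
#'
#' Welch-type pairwise tests robust to unequal variances: for each pair the
#' statistic \eqn{t = (m_i - m_j) / \sqrt{s_i^2/n_i + s_j^2/n_j}} with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized-range
#' distribution via \eqn{q = \sqrt{2} |t|} with `k` groups.
#'
#' @param values numeric response vector.
#' @param group factor of group membership.
#' @return data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `t`, `df`, `p` (Games-Howell) and `p_bonferroni`
#'   (`min(1, p * m)` over the `m` pairs).
#' @export
games_howell <- function(values, group) {
  group <- droplevels(as.factor(group))
  lev <- levels(group)
  k <- length(lev)
  if (k < 2)
    cranio_abort("cranio_input_error", "need at least two groups")
  ns <- tapply(values, group, length)
  ms <- tapply(values, group, mean)
  vs <- tapply(values, group, stats::var)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    if (se2 <= 0)
      cranio_abort("cranio_degenerate_variance",
                   "zero variance in both groups of a pair")
    tstat <- (ms[i] - ms[j]) / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                   (vs[j] / ns[j])^2 / (ns[j] - 1))
    p_gh <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df,
                          lower.tail = FALSE)
    data.frame(group1 = lev[i], group2 = lev[j],
               diff = unname(ms[i] - ms[j]), se = unname(sqrt(se2)),
               t = unname(tstat), df = unname(df), p = unname(p_gh),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * m)
  res
}

#' Omnibus and post hoc group comparison
#'
#' The full comparison chain for per-subject summary values: one-way ANOVA
#' (equal-variance F test), Levene's test for homogeneity of variances
#' (classical mean-centered version: ANOVA on absolute deviations from
#' group means), and Games-Howell pairwise comparisons with
#' Bonferroni-adjusted p values. Significance is flagged on the adjusted
#' value at `alpha`.
#'
#' @param values numeric response vector (e.g. per-subject mean per-degree
#'   range).
#' @param group factor of group membership; >= 2 groups of >= 2 subjects.
#' @param alpha significance level for the pairwise flags (default 0.05).
#' @return list of class `cranio_comparison`: `anova` (statistic, df, p),
#'   `levene` (statistic, df, p), `pairwise` (the [games_howell()] table
#'   with a `significant` flag), `alpha`.
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    cranio_abort("cranio_singleton_group", "need at least two groups")
  ns <- tapply(values, group, length)
  if (any(ns < 2))
    cranio_abort("cranio_singleton_group",
                 "every group needs at least two subjects")
  vs <- tapply(values, group, stats::var)
  if (all(vs == 0))
    cranio_abort("cranio_degenerate_variance", "no within-group variance")

  an <- stats::oneway.test(values ~ group, var.equal = TRUE)
  z <- abs(values - stats::ave(values, group))
  lv <- stats::oneway.test(z ~ group, var.equal = TRUE)
  pw <- games_howell(values, group)
  pw$significant <- pw$p_bonferroni < alpha
  structure(list(
    anova = list(F = unname(an$statistic), df = unname(an$parameter),
                 p = unname(an$p.value)),
    levene = list(W = unname(lv$statistic), df = unname(lv$parameter),
                  p = unname(lv$p.value)),
    pairwise = pw, alpha = alpha
  ), class = "cranio_comparison")
}

#' @export
print.cranio_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat(sprintf("Levene (mean-centered): W(%g, %g) = %.3f, p = %.4g\n",
              x$levene$df[1], x$levene$df[2], x$levene$W, x$levene$p))
  cat(sprintf("Games-Howell post hoc (Bonferroni-adjusted, alpha = %g):\n",
              x$alpha))
  print(x$pairwise, digits = 4, row.names = FALSE)
  invisible(x)
}
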