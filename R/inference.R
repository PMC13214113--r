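# Group-level inference on decoding outputs: above-chance test of mean
# AUCs, coefficient-consistency test, vigor correlations (plain and
# partial), and the acceleration artifact-control correlation.

#' Group test of mean AUCs against chance
#'
#' One-sample t-test of per-subject mean AUC values against 0.5, with
#' Cohen's dz and the mean delta AUC with its 95% CI.
#'
#' @param mean_aucs per-subject mean AUC values.
#' @return list: `t`, `p`, `d`, `delta_auc_mean`, `ci`, `n`.
#' @export
group_auc_test <- function(mean_aucs) {
  mean_aucs <- mean_aucs[is.finite(mean_aucs)]
  if (length(mean_aucs) < 5L) stop("group_auc_test: need >= 5 subjects")
  if (stats::sd(mean_aucs) == 0)
    stop("group_auc_test: zero variance in AUCs (degenerate input)")
  tt <- stats::t.test(mean_aucs, mu = 0.5)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = (mean(mean_aucs) - 0.5) / stats::sd(mean_aucs),
       delta_auc_mean = mean(mean_aucs) - 0.5,
       ci = unname(tt$conf.int) - 0.5, n = length(mean_aucs))
}

#' Coefficient-consistency test across subjects
#'
#' Two-sided one-sample t-test of the mean standardized regression
#' coefficients (above-chance subjects only, per the exclusion rule)
#' against zero, with the positive/negative sign split.
#'
#' @param mean_coefficients per-subject mean coefficients, already
#'   restricted to above-chance subjects.
#' @return list: `t`, `p`, `d`, `prop_negative`, `prop_positive`, `n`;
#'   all NA with a warning when fewer than 5 subjects remain.
#' @export
coefficient_consistency_test <- function(mean_coefficients) {
  x <- mean_coefficients[is.finite(mean_coefficients)]
  if (length(x) < 5L) {
    warning("coefficient_consistency_test: fewer than 5 subjects; test skipped")
    return(list(t = NA_real_, p = NA_real_, d = NA_real_,
                prop_negative = NA_real_, prop_positive = NA_real_,
                n = length(x)))
  }
  tt <- stats::t.test(x, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = mean(x) / stats::sd(x),
       prop_negative = mean(x < 0), prop_positive = mean(x > 0),
       n = length(x))
}

#' Correlation of decoding coefficients with behavioral vigor differences
#'
#' Pearson correlation between per-subject mean regression coefficients
#' and the Slow-Fast difference in RT+MT (or MT or RT), with a one-sided
#' p for the expected negative direction.
#'
#' @param mean_coefficients per-subject mean coefficients.
#' @param behavior_diff per-subject Slow-Fast behavioral differences,
#'   aligned with `mean_coefficients`.
#' @param alternative `"less"` (negative expected, default), `"greater"`,
#'   or `"two.sided"`.
#' @return list: `r`, `p`, `n`, `alternative`.
#' @export
vigor_correlation <- function(mean_coefficients, behavior_diff,
                              alternative = "less") {
  ok <- is.finite(mean_coefficients) & is.finite(behavior_diff)
  x <- mean_coefficients[ok]; y <- behavior_diff[ok]
  if (length(x) < 5L) stop("vigor_correlation: need >= 5 subjects")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       alternative = alternative)
}

#' Partial correlation controlling for a covariate
#'
#' Residualizes both the coefficient vector and the behavioral difference
#' on the control variable by least squares, correlates the residuals,
#' and tests one-sided with df = n - 3.
#'
#' @param mean_coefficients,behavior_diff aligned per-subject vectors.
#' @param control covariate (e.g. the power-based coefficients).
#' @param alternative as in [vigor_correlation()].
#' @return list: `r`, `p`, `df`, `n`, `alternative`.
#' @export
partial_vigor_correlation <- function(mean_coefficients, behavior_diff,
                                      control, alternative = "less") {
  ok <- is.finite(mean_coefficients) & is.finite(behavior_diff) &
    is.finite(control)
  x <- mean_coefficients[ok]; y <- behavior_diff[ok]; z <- control[ok]
  n <- length(x)
  if (n < 5L) stop("partial_vigor_correlation: need >= 5 subjects")
  if (stats::sd(z) > 0) {
    cx <- abs(stats::cor(x, z))
    if (cx > 0.999)
      warning("partial_vigor_correlation: control nearly collinear with target")
  }
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1))
    return(list(r = 0, p = NA_real_, df = n - 3, n = n,
                alternative = alternative))
  r <- stats::cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  p <- switch(alternative,
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              two.sided = 2 * stats::pt(-abs(tstat), df))
  list(r = r, p = p, df = df, n = n, alternative = alternative)
}

#' Artifact-control correlation: trial-wise |acceleration| vs beta feature
#'
#' Per subject, the Pearson correlation between trial-wise mean absolute
#' acceleration and the trial-mean beta feature; then a one-sample t-test
#' of the per-subject r values against zero. Subjects with a constant
#' feature are skipped with a message.
#'
#' @param acc_by_subject list of per-trial mean |acc| vectors.
#' @param feature_by_subject list of aligned per-trial feature vectors.
#' @return list: `r_values`, `t`, `p`, `n`.
#' @export
artifact_control_correlation <- function(acc_by_subject,
                                         feature_by_subject) {
  stopifnot(length(acc_by_subject) == length(feature_by_subject))
  rs <- numeric(0)
  for (s in seq_along(acc_by_subject)) {
    a <- acc_by_subject[[s]]; f <- feature_by_subject[[s]]
    ok <- is.finite(a) & is.finite(f)
    if (stats::sd(f[ok]) == 0 || stats::sd(a[ok]) == 0) {
      message("artifact_control_correlation: subject ", s,
              " skipped (constant input)")
      next
    }
    rs <- c(rs, stats::cor(a[ok], f[ok]))
  }
  if (length(rs) < 2L || stats::sd(rs) < 1e-10)
    return(list(r_values = rs, t = NA_real_, p = NA_real_, n = length(rs)))
  tt <- stats::t.test(rs, mu = 0)
  list(r_values = rs, t = unname(tt$statistic), p = tt$p.value,
       n = length(rs))
}
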