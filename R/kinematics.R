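# Behavioral feature extraction from luxmeter/accelerometer traces and the
# behavioral statistics: per-trial RT, MT, movement amplitude and mean
# absolute acceleration; MAD outlier marking; paired comparisons with a
# normality gate.

#' Detect post-cue luminosity peaks in one trial
#'
#' Local maxima above a relative prominence threshold (fraction of the
#' trial's dynamic range above its minimum), separated by at least
#' `min_distance` seconds, restricted to at or after the go cue. The
#' luminosity peaks mark the moments when the hand is fully open: with the
#' hand starting open, a four-repetition trial produces five post-cue
#' peaks (the RT anchor plus four movement intervals).
#'
#' @param lux_trial numeric luminosity series.
#' @param fs_behav sampling rate, Hz.
#' @param go_cue_index go-cue sample index.
#' @param n_required required peak count (default 5); fewer marks the
#'   trial invalid rather than raising an error.
#' @param prominence relative threshold, fraction of dynamic range.
#' @param min_distance minimum inter-peak separation, seconds.
#' @return integer vector of peak sample indices (strictly increasing, all
#'   `>= go_cue_index`), or `NULL` with attribute handling via `valid`:
#'   the return is a list with `peaks` and `valid`.
#' @export
detect_luminosity_peaks <- function(lux_trial, fs_behav, go_cue_index,
                                    n_required = 5,
                                    prominence = 0.5,
                                    min_distance = 0.1) {
  rng <- range(lux_trial)
  if (diff(rng) <= 0)
    return(list(peaks = integer(0), valid = FALSE))
  thr <- rng[1] + prominence * diff(rng)
  pk <- pracma::findpeaks(lux_trial, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_distance * fs_behav)))
  if (is.null(pk))
    return(list(peaks = integer(0), valid = FALSE))
  idx <- sort(pk[, 2])
  idx <- idx[idx >= go_cue_index]
  if (length(idx) < n_required)
    return(list(peaks = idx, valid = FALSE))
  list(peaks = idx[seq_len(n_required)], valid = TRUE)
}

#' Per-trial behavioral variables from detected peaks
#'
#' MT is the mean of the four inter-peak intervals; RT the time from go
#' cue to the first peak; amplitude the mean over repetitions of the
#' luminosity range within each repetition segment (from a peak to the
#' sample before the next peak); mean absolute acceleration is averaged
#' from the go cue to the last peak.
#'
#' @param peaks integer peak indices (as from [detect_luminosity_peaks()]).
#' @param lux_trial,acc_trial the trial's traces.
#' @param fs_behav sampling rate, Hz.
#' @param go_cue_index go-cue sample index.
#' @return named numeric: `MT`, `RT`, `amplitude`, `mean_abs_acc` (s, s,
#'   a.u., a.u.).
#' @export
compute_trial_behavior <- function(peaks, lux_trial, acc_trial, fs_behav,
                                   go_cue_index) {
  if (length(peaks) < 2L || any(diff(peaks) <= 0))
    stop("compute_trial_behavior: peaks must be strictly increasing, >= 2")
  mt <- mean(diff(peaks)) / fs_behav
  rt <- (peaks[1] - go_cue_index) / fs_behav
  amps <- vapply(seq_len(length(peaks) - 1L), function(k) {
    seg <- lux_trial[peaks[k]:(peaks[k + 1L] - 1L)]
    max(seg) - min(seg)
  }, 0)
  acc_seg <- acc_trial[go_cue_index:peaks[length(peaks)]]
  c(MT = mt, RT = rt, amplitude = mean(amps),
    mean_abs_acc = mean(abs(acc_seg)))
}

#' Mark outliers by the 3xMAD rule
#'
#' Flags values with `|x - median| > n_mad * MAD`, where MAD is the raw
#' median absolute deviation (no normal-consistency constant). A zero MAD
#' flags every value deviating from the median. NAs are never flagged.
#'
#' @param x numeric values (one subject x condition group).
#' @param n_mad multiplier (3 by default).
#' @return logical mask, `TRUE` = outlier.
#' @export
mark_behavioral_outliers <- function(x, n_mad = 3) {
  if (all(is.na(x))) {
    warning("mark_behavioral_outliers: all values are NA")
    return(rep(FALSE, length(x)))
  }
  med <- stats::median(x, na.rm = TRUE)
  m <- mad_raw(x)
  out <- abs(x - med) > n_mad * m
  out[is.na(out)] <- FALSE
  out
}

#' Paired comparison with normality gate
#'
#' Shapiro-Wilk is applied to the paired differences; if `p > 0.05` a
#' paired t-test is used with Cohen's dz (`mean(diff)/sd(diff)`),
#' otherwise a Wilcoxon signed-rank test with the matched-pairs
#' rank-biserial correlation `(W+ - W-)/(W+ + W-)`.
#'
#' @param a,b paired per-subject values.
#' @param gate `"differences"` (default) applies the normality gate to the
#'   paired differences; `"both"` requires both margins to pass.
#' @return list: `test` ("paired-t" or "wilcoxon"), `statistic`, `p`,
#'   `effect_size`, `effect_type` ("dz" or "rank-biserial"), `shapiro_p`.
#' @export
paired_compare <- function(a, b, gate = c("differences", "both")) {
  gate <- match.arg(gate)
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 5L) stop("paired_compare: need at least 5 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("paired_compare: zero-variance differences (degenerate input)")
  sp <- stats::shapiro.test(d)$p.value
  normal <- sp > 0.05
  if (gate == "both")
    normal <- normal && stats::shapiro.test(a)$p.value > 0.05 &&
      stats::shapiro.test(b)$p.value > 0.05
  if (normal) {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(test = "paired-t", statistic = unname(tt$statistic),
         p = tt$p.value, effect_size = mean(d) / stats::sd(d),
         effect_type = "dz", shapiro_p = sp, n = length(a))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    wplus <- unname(wt$statistic)
    nz <- sum(d != 0)
    wtot <- nz * (nz + 1) / 2
    r_rb <- (wplus - (wtot - wplus)) / wtot
    list(test = "wilcoxon", statistic = wplus, p = wt$p.value,
         effect_size = r_rb, effect_type = "rank-biserial", shapiro_p = sp,
         n = length(a))
  }
}

#' Extract the behavioral table of a cohort subject
#'
#' Runs peak detection and per-trial extraction over all trials, marks
#' per-variable outliers within subject x condition (flagged, set to NA in
#' the `*_clean` columns, never dropped from the raw columns).
#'
#' @param kin a [kinematic_traces()].
#' @param subject subject label for the output table.
#' @return data.frame, one row per trial: condition, validity, MT, RT,
#'   amplitude, mean_abs_acc, vigor proxy (RT+MT) and outlier flags.
#' @export
behavior_table <- function(kin, subject = "sub-01") {
  n <- length(kin$lux)
  vars <- c("MT", "RT", "amplitude", "mean_abs_acc")
  out <- data.frame(subject = subject, trial = seq_len(n),
                    condition = kin$labels, valid = FALSE,
                    MT = NA_real_, RT = NA_real_, amplitude = NA_real_,
                    mean_abs_acc = NA_real_, stringsAsFactors = FALSE)
  for (tr in seq_len(n)) {
    det <- detect_luminosity_peaks(kin$lux[[tr]], kin$fs_behav,
                                   kin$go_cue_index[tr])
    if (!det$valid) next
    out$valid[tr] <- TRUE
    out[tr, vars] <- compute_trial_behavior(det$peaks, kin$lux[[tr]],
                                            kin$acc[[tr]], kin$fs_behav,
                                            kin$go_cue_index[tr])
  }
  out$vigor_proxy <- out$RT + out$MT
  for (v in vars) {
    flag <- rep(FALSE, n)
    for (cond in unique(out$condition)) {
      i <- which(out$condition == cond & out$valid)
      if (length(i) >= 3L)
        flag[i] <- mark_behavioral_outliers(out[[v]][i])
    }
    out[[paste0(v, "_outlier")]] <- flag
    out[[paste0(v, "_clean")]] <- ifelse(flag | !out$valid, NA, out[[v]])
  }
  out
}

#' Subject x condition behavioral summaries
#'
#' Means of the cleaned variables per subject and condition, plus the
#' Slow-Fast differences in RT, MT and the vigor proxy RT+MT.
#'
#' @param behavior data.frame from [behavior_table()] (possibly several
#'   subjects row-bound).
#' @return list with `summary` (subject x condition means) and `diffs`
#'   (per subject: Slow - Fast differences).
#' @export
summarize_behavior <- function(behavior) {
  vars <- c("MT_clean", "RT_clean", "amplitude_clean", "mean_abs_acc_clean")
  agg <- stats::aggregate(behavior[vars],
                          by = list(subject = behavior$subject,
                                    condition = behavior$condition),
                          FUN = mean, na.rm = TRUE)
  names(agg) <- sub("_clean", "", names(agg))
  agg$vigor_proxy <- agg$RT + agg$MT
  wide <- function(v) {
    f <- agg[agg$condition == "Fast", c("subject", v)]
    s <- agg[agg$condition == "Slow", c("subject", v)]
    m <- merge(f, s, by = "subject", suffixes = c("_fast", "_slow"))
    m[[paste0(v, "_diff")]] <- m[[paste0(v, "_slow")]] - m[[paste0(v, "_fast")]]
    m
  }
  diffs <- Reduce(function(a, b) merge(a, b, by = "subject"),
                  lapply(c("RT", "MT", "vigor_proxy"), wide))
  list(summary = agg, diffs = diffs)
}
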