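# End-to-end orchestration: configuration, the behavior -> features ->
# screening -> group stats -> decoding -> inference chain, and report
# serialization. Every stochastic stage is seeded from the master seed.

#' Run configuration
#'
#' @param band beta sub-band name (`"standard"`, `"low"`, `"high"`).
#' @param analyses which feature/space paths to run: any of
#'   `"source-icoh"`, `"sensor-power"`, `"source-power"`.
#' @param candidates named list mapping each analysis to a candidate
#'   preset name (see [candidate_preset()]); validated here, before any
#'   compute.
#' @param window_subset `"all"` or `"pre-go-cue"` (the first four
#'   analysis windows).
#' @param min_gain,max_groups,n_folds,n_boot,inverse_reg decoding
#'   parameters.
#' @param coding outcome coding (see [cv_auc()]).
#' @param alpha,n_perm,adjacency_radius group-statistics parameters.
#' @param seed master seed; all stage seeds are fanned out from it.
#' @return a `run_config`.
#' @export
run_config <- function(band = "standard",
                       analyses = c("source-icoh", "sensor-power"),
                       candidates = list("source-icoh" = "fronto-parietal-21",
                                         "sensor-power" = "left-central-21",
                                         "source-power" = "fronto-parietal-21"),
                       window_subset = c("all", "pre-go-cue"),
                       min_gain = 0.002, max_groups = 3, n_folds = 5,
                       n_boot = 1000, inverse_reg = 1,
                       coding = "fast1",
                       alpha = 0.05, n_perm = 1000,
                       adjacency_radius = 0.02,
                       seed = 1L) {
  window_subset <- match.arg(window_subset)
  known <- c("source-icoh", "sensor-power", "source-power")
  if (!all(analyses %in% known))
    stop("run_config: unknown analysis: ",
         paste(setdiff(analyses, known), collapse = ", "))
  for (a in analyses) {
    if (is.null(candidates[[a]]))
      stop("run_config: no candidate preset for analysis ", a)
    candidate_preset(candidates[[a]])  # errors on unknown preset
  }
  structure(list(
    band = band, analyses = analyses, candidates = candidates,
    window_subset = window_subset, min_gain = min_gain,
    max_groups = max_groups, n_folds = n_folds, n_boot = n_boot,
    inverse_reg = inverse_reg, coding = coding, alpha = alpha,
    n_perm = n_perm, adjacency_radius = adjacency_radius,
    seed = as.integer(seed)
  ), class = "run_config")
}

window_subset_idx <- function(window_subset, n_windows = 7L) {
  if (window_subset == "pre-go-cue") 1:4 else seq_len(n_windows)
}

restrict_windows <- function(tensor, idx) {
  out <- tensor
  out$values <- tensor$values[, , idx, drop = FALSE]
  out
}

#' Source-space feature tensors for one subject
#'
#' Filter -> decimate -> symmetric orthogonalization (per trial, on the
#' band-filtered real signals) -> Hilbert -> trim, then the seed-based
#' iCoh tensor; source power is computed from the non-orthogonalized
#' analytic signals.
#'
#' @param parcels raw real [parcel_tc()] at the acquisition rate.
#' @param band [band_def()].
#' @param metrics subset of `c("icoh", "power")`.
#' @return named list of [feature_tensor()]s (`icoh`, `power`).
#' @export
source_features <- function(parcels, band, metrics = c("icoh", "power")) {
  filt <- band_filter(parcels, band)
  out <- list()
  if ("icoh" %in% metrics) {
    orth <- symmetric_orthogonalize(filt)$parcels
    out$icoh <- seed_icoh_tensor(hilbert_parcels(orth))
  }
  if ("power" %in% metrics)
    out$power <- analytic_power(hilbert_parcels(filt))
  out
}

#' Run the full analysis on a cohort
#'
#' Behavior -> features -> MAD screening -> group statistics -> per-subject
#' decoding -> group inference, returning one report list (JSON-ready,
#' deterministic for a fixed master seed).
#'
#' @param cohort a [simulate_cohort()] / [read_cohort()] cohort.
#' @param config a [run_config()].
#' @return a `run_report` list.
#' @export
run_end_to_end <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "run_config"))
  band <- beta_band(config$band)
  n_sub <- length(cohort$subjects)
  subjects <- cohort$truth$subjects$subject
  widx <- window_subset_idx(config$window_subset)

  ## ---- behavior -------------------------------------------------------
  behav <- do.call(rbind, lapply(seq_len(n_sub), function(s)
    behavior_table(cohort$subjects[[s]]$kinematics, subjects[s])))
  bsum <- summarize_behavior(behav)
  wide_var <- function(v) {
    f <- bsum$summary[bsum$summary$condition == "Fast", ]
    s <- bsum$summary[bsum$summary$condition == "Slow", ]
    list(fast = f[[v]][match(subjects, f$subject)],
         slow = s[[v]][match(subjects, s$subject)])
  }
  behavior_tests <- lapply(c("MT", "RT", "amplitude", "mean_abs_acc"),
                           function(v) {
    w <- wide_var(v)
    c(list(variable = v), paired_compare(w$fast, w$slow))
  })

  ## ---- features -------------------------------------------------------
  need_sensor <- "sensor-power" %in% config$analyses
  need_icoh <- "source-icoh" %in% config$analyses
  need_spower <- "source-power" %in% config$analyses
  tensors <- list()
  for (s in seq_len(n_sub)) {
    sub <- cohort$subjects[[s]]
    tl <- list()
    if (need_icoh || need_spower) {
      sf <- source_features(sub$parcels, band,
                            metrics = c(if (need_icoh) "icoh",
                                        if (need_spower) "power"))
      if (need_icoh) tl[["source-icoh"]] <- sf$icoh
      if (need_spower) tl[["source-power"]] <- sf$power
    }
    if (need_sensor) {
      if (is.null(sub$epochs))
        stop("run_end_to_end: sensor analysis requested but cohort has no epochs")
      tl[["sensor-power"]] <- morlet_band_power(sub$epochs, band)
    }
    tensors[[s]] <- tl
  }

  ## ---- screening + group stats ---------------------------------------
  group <- list()
  for (an in config$analyses) {
    screened <- lapply(seq_len(n_sub), function(s)
      screen_trials(tensors[[s]][[an]]))
    cmeans <- lapply(screened, function(z) tensor_condition_means(z$tensor))
    units <- tensors[[1]][[an]]$unit_ids
    nw <- dim(tensors[[1]][[an]]$values)[3]
    fast_w <- lapply(seq_len(nw), function(w)
      t(vapply(cmeans, function(m) m$Fast[, w], numeric(length(units)))))
    slow_w <- lapply(seq_len(nw), function(w)
      t(vapply(cmeans, function(m) m$Slow[, w], numeric(length(units)))))
    tmat <- vapply(seq_len(nw), function(w) {
      d <- fast_w[[w]] - slow_w[[w]]
      colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n_sub))
    }, numeric(length(units)))
    rownames(tmat) <- units
    res <- list(
      removal_fraction = mean(vapply(screened, `[[`, 0, "removal_fraction")),
      t_matrix = tmat,
      top_units = rank_parcels_by_t(tmat, 5)
    )
    if (an == "sensor-power") {
      adj <- build_adjacency(cohort$subjects[[1]]$epochs$positions,
                             config$adjacency_radius)
      res$cluster_tests <- lapply(seq_len(nw), function(w)
        paired_cluster_permutation(fast_w[[w]], slow_w[[w]], adj,
                                   alpha = config$alpha,
                                   n_perm = config$n_perm,
                                   seed = fan_seed(config$seed, 200L + w)))
    }
    if (an == "source-icoh") {
      subset <- candidate_preset(config$candidates[[an]], units)
      dmean <- t(vapply(seq_len(n_sub), function(s) {
        di <- rowMeans(cmeans[[s]]$Fast[subset, , drop = FALSE] -
                         cmeans[[s]]$Slow[subset, , drop = FALSE])
        di
      }, numeric(length(subset))))
      res$sign_proportion <- sign_proportion_permutation(
        dmean, n_perm = config$n_perm, seed = fan_seed(config$seed, 300L))
    }
    group[[an]] <- res
  }

  ## ---- decoding -------------------------------------------------------
  decoding <- list()
  for (an in config$analyses) {
    cand_all <- candidate_preset(config$candidates[[an]],
                                 tensors[[1]][[an]]$unit_ids)
    if (is.null(cand_all)) cand_all <- tensors[[1]][[an]]$unit_ids
    results <- lapply(seq_len(n_sub), function(s) {
      tens <- restrict_windows(tensors[[s]][[an]], widx)
      decode_subject(tens, cand_all,
                     n_boot = config$n_boot, min_gain = config$min_gain,
                     max_groups = config$max_groups,
                     n_folds = config$n_folds,
                     inverse_reg = config$inverse_reg,
                     seed = fan_seed(config$seed, 1000L + s),
                     coding = config$coding, subject = subjects[s])
    })
    decoding[[an]] <- list(
      subjects = results,
      selection_frequency = selection_frequency(results, cand_all)
    )
  }

  ## ---- inference ------------------------------------------------------
  diffs <- bsum$diffs[match(subjects, bsum$diffs$subject), ]
  inference <- list()
  for (an in config$analyses) {
    res <- decoding[[an]]$subjects
    aucs <- vapply(res, `[[`, 0, "mean_auc")
    coefs <- vapply(res, `[[`, 0, "mean_coefficient")
    above <- vapply(res, `[[`, TRUE, "above_chance")
    cons <- coefficient_consistency_test(coefs[above])
    inf <- list(
      auc_test = group_auc_test(aucs),
      consistency = cons,
      n_above_chance = sum(above)
    )
    use <- above & is.finite(coefs)
    if (sum(use) >= 5) {
      inf$vigor_rtmt <- vigor_correlation(coefs[use],
                                          diffs$vigor_proxy_diff[use])
      inf$vigor_mt <- vigor_correlation(coefs[use], diffs$MT_diff[use])
      inf$vigor_rt <- vigor_correlation(coefs[use], diffs$RT_diff[use])
    }
    # artifact control: trial-wise |acc| vs trial-mean feature
    acc_by <- lapply(seq_len(n_sub), function(s) {
      b <- behav[behav$subject == subjects[s], ]
      b$mean_abs_acc
    })
    feat_by <- lapply(seq_len(n_sub), function(s)
      apply(tensors[[s]][[an]]$values, 1, mean, na.rm = TRUE))
    inf$artifact_control <- artifact_control_correlation(acc_by, feat_by)
    inference[[an]] <- inf
  }
  if (all(c("source-icoh", "sensor-power") %in% config$analyses)) {
    ic <- decoding[["source-icoh"]]$subjects
    pw <- decoding[["sensor-power"]]$subjects
    ci <- vapply(ic, `[[`, 0, "mean_coefficient")
    cp <- vapply(pw, `[[`, 0, "mean_coefficient")
    use <- vapply(ic, `[[`, TRUE, "above_chance") & is.finite(ci) &
      is.finite(cp)
    if (sum(use) >= 5)
      inference$partial_icoh_vs_power <- partial_vigor_correlation(
        ci[use], diffs$vigor_proxy_diff[use], cp[use])
  }

  structure(list(
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    n_subjects = n_sub,
    behavior = list(tests = behavior_tests,
                    diffs = diffs,
                    summary = bsum$summary),
    group_stats = group,
    decoding = lapply(decoding, function(d) list(
      table = data.frame(
        subject = vapply(d$subjects, `[[`, "", "subject"),
        mean_auc = vapply(d$subjects, `[[`, 0, "mean_auc"),
        delta_auc = vapply(d$subjects, `[[`, 0, "delta_auc"),
        ci_lo = vapply(d$subjects, function(r) r$bootstrap_ci[1], 0),
        ci_hi = vapply(d$subjects, function(r) r$bootstrap_ci[2], 0),
        mean_coefficient = vapply(d$subjects, `[[`, 0, "mean_coefficient"),
        above_chance = vapply(d$subjects, `[[`, TRUE, "above_chance"),
        selected = vapply(d$subjects, function(r)
          paste(r$selected_groups, collapse = "+"), ""),
        stringsAsFactors = FALSE),
      selection_frequency = d$selection_frequency)),
    inference = inference
  ), class = "run_report")
}

#' Serialize a run report to JSON
#'
#' @param report a [run_end_to_end()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(clean_for_json(unclass(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

clean_for_json <- function(x) {
  if (inherits(x, "band_def")) return(unclass(x))
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, clean_for_json))
  x
}
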