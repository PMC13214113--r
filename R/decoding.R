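# Subject-specific decoding of Fast vs Slow: grouped sequential forward
# selection around L1-regularized logistic regression with leakage-safe
# stratified cross-validation and bootstrap stability.
#
# Outcome coding: by default Fast = 1, Slow = 0, so a NEGATIVE standardized
# coefficient means the feature is LOWER in Fast trials. The opposite
# coding is available via `coding = "slow1"`.

#' Feature matrix of a tensor restricted to candidate groups
#'
#' Each group is one spatial unit with all its analysis windows, so a
#' group contributes `n_windows` columns.
#'
#' @param tensor a [feature_tensor()].
#' @param groups unit ids to include (default: all units).
#' @return numeric matrix trials x (groups * windows) with `unit|window`
#'   column names and a `groups` attribute mapping columns to units.
#' @export
feature_matrix <- function(tensor, groups = tensor$unit_ids) {
  miss <- setdiff(groups, tensor$unit_ids)
  if (length(miss) > 0)
    stop("feature_matrix: unknown units: ", paste(miss, collapse = ", "))
  nw <- dim(tensor$values)[3]
  cols <- lapply(groups, function(g) {
    m <- tensor$values[, match(g, tensor$unit_ids), , drop = TRUE]
    matrix(m, ncol = nw)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- as.vector(t(outer(groups, seq_len(nw),
                                   function(g, w) paste0(g, "|w", w))))
  attr(x, "groups") <- rep(groups, each = nw)
  x
}

#' Stratified fold assignment
#' @keywords internal
#' @noRd
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  folds
}

#' Leakage-safe cross-validated AUC of an L1 logistic model
#'
#' Stratified folds; within each training fold, trials are first cleaned
#' per condition by the 3xMAD rule (a training trial is dropped when any
#' of its features is flagged), features are z-scored with training-fold
#' statistics (applied unchanged to the test fold), and an L1 logistic
#' model at fixed regularization is fit. Test-fold data is used for
#' prediction only. A fold losing a class after cleaning triggers a fold
#' re-draw with a new seed (logged via message); persistent failure is an
#' error.
#'
#' @param x feature matrix, trials x features.
#' @param y condition labels (`"Fast"`/`"Slow"`) or 0/1 outcome.
#' @param n_folds folds (5).
#' @param inverse_reg inverse regularization strength C; the glmnet
#'   lambda is `1/(C * n_train)`.
#' @param n_mad MAD multiplier of the training-fold trial cleaning.
#' @param seed RNG seed for the fold draw.
#' @param folds optional fixed fold assignment (overrides the draw).
#' @param coding `"fast1"` (default) or `"slow1"`.
#' @return list: `mean_auc`, `fold_aucs`, `coefficients` (folds x
#'   features, standardized scale), `fold_stats` (training means/sds),
#'   `folds`.
#' @export
cv_auc <- function(x, y, n_folds = 5, inverse_reg = 1, n_mad = 3,
                   seed = 1L, folds = NULL, coding = c("fast1", "slow1")) {
  coding <- match.arg(coding)
  x <- as.matrix(x)
  yb <- encode_outcome(y, coding)
  if (length(unique(yb)) < 2L) stop("cv_auc: both classes required")
  if (any(!is.finite(x))) stop("cv_auc: features must be finite")
  for (attempt in 0:4) {
    if (is.null(folds) || attempt > 0)
      fl <- stratified_folds(yb, n_folds, fan_seed(seed, attempt))
    else fl <- folds
    res <- try(cv_auc_run(x, yb, fl, n_folds, inverse_reg, n_mad),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      if (attempt > 0)
        message("cv_auc: fold re-drawn ", attempt, " time(s) after class loss")
      res$folds <- fl
      return(res)
    }
    if (!grepl("class lost", res)) stop(res)
  }
  stop("cv_auc: persistent class loss after MAD cleaning across fold re-draws")
}

encode_outcome <- function(y, coding) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("Fast", "Slow")))
      stop("labels must be 'Fast'/'Slow' or 0/1")
    if (coding == "fast1") as.integer(y == "Fast") else as.integer(y == "Slow")
  } else as.integer(y)
}

cv_auc_run <- function(x, yb, fl, n_folds, inverse_reg, n_mad) {
  fold_aucs <- numeric(n_folds)
  coefs <- matrix(0, n_folds, ncol(x),
                  dimnames = list(NULL, colnames(x)))
  fold_stats <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(fl != f)
    te <- which(fl == f)
    keep <- tr
    for (cl in c(0L, 1L)) {
      idx <- tr[yb[tr] == cl]
      if (length(idx) >= 3L) {
        xi <- x[idx, , drop = FALSE]
        med <- col_medians(xi)
        dev <- abs(sweep(xi, 2, med))
        m <- col_medians(dev)
        # zero-MAD features (degenerate cells, e.g. duplicated bootstrap
        # trials) carry no trial-level outlier information: skipped
        use <- m > 0
        flag <- if (any(use))
          rowSums(dev[, use, drop = FALSE] >
                    rep(n_mad * m[use], each = nrow(dev))) > 0
        else rep(FALSE, nrow(dev))
        keep <- setdiff(keep, idx[flag])
      }
    }
    if (min(table(factor(yb[keep], levels = c(0L, 1L)))) < 2L)
      stop("class lost in fold ", f)
    xk <- x[keep, , drop = FALSE]
    nk <- nrow(xk)
    mu <- colMeans(xk)
    sdv <- sqrt(pmax(colSums(xk^2) - nk * mu^2, 0) / (nk - 1))
    if (all(sdv < 1e-300)) {  # no information at all: chance, null model
      fold_aucs[f] <- 0.5
      fold_stats[[f]] <- list(mu = mu, sd = rep(1, length(mu)),
                              n_train = nk)
      next
    }
    sdv[sdv < 1e-300] <- 1
    zscore <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
    xfit <- zscore(xk)
    if (ncol(xfit) == 1L) xfit <- cbind(xfit, 0)  # glmnet needs >= 2 columns
    # a short warm-started path down to the target lambda: single-lambda
    # fits are fragile on near-separable resamples (they can hit maxit
    # and return an empty model)
    lam <- 1 / (inverse_reg * nk)
    fit <- withCallingHandlers(
      glmnet::glmnet(xfit, yb[keep],
                     family = "binomial", alpha = 1,
                     lambda = lam * c(16, 8, 4, 2, 1),
                     standardize = FALSE),
      warning = function(w) {
        # small training classes after MAD cleaning are expected and
        # handled by the fold re-draw logic; silence the advisory
        if (grepl("fewer than 8|dangerous ground", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    # last path entry = the target lambda (glmnet may truncate the path
    # only on non-convergence, in which case the closest fit is used)
    k <- length(fit$lambda)
    co <- c(fit$a0[k], as.numeric(fit$beta[, k]))[seq_len(ncol(x) + 1L)]
    scores <- as.numeric(cbind(1, zscore(x[te, , drop = FALSE])) %*% co)
    fold_aucs[f] <- auc_rank(scores, yb[te])
    coefs[f, ] <- co[-1]
    fold_stats[[f]] <- list(mu = mu, sd = sdv, n_train = nk)
  }
  list(mean_auc = mean(fold_aucs), fold_aucs = fold_aucs,
       coefficients = coefs, fold_stats = fold_stats)
}

#' Grouped sequential forward selection
#'
#' Greedy forward search over spatial feature groups: at each step every
#' remaining candidate is evaluated by [cv_auc()] on the current selection
#' plus that candidate (fixed folds throughout the search); the best
#' candidate is adopted iff the gain is at least `min_gain` (at the first
#' step: iff its AUC beats chance by `min_gain`). Stops at `max_groups` or
#' when no candidate qualifies. Ties are broken by candidate order.
#'
#' @param tensor a [feature_tensor()].
#' @param candidates candidate unit ids.
#' @param min_gain minimum AUC improvement (0.002).
#' @param max_groups maximum selected groups (3).
#' @param n_folds,inverse_reg,n_mad,coding passed to [cv_auc()].
#' @param seed RNG seed (fold draw).
#' @return list: `selected` (unit ids, possibly empty), `cv` (final
#'   [cv_auc()] result of the selected model; for an empty selection, of
#'   the best single rejected model, with `empty_selection = TRUE`),
#'   `trace` (per-step best AUC).
#' @export
sfs_grouped <- function(tensor, candidates, min_gain = 0.002,
                        max_groups = 3, n_folds = 5, inverse_reg = 1,
                        n_mad = 3, seed = 1L,
                        coding = c("fast1", "slow1")) {
  coding <- match.arg(coding)
  stopifnot(length(candidates) >= 1L)
  yb <- encode_outcome(tensor$labels, coding)
  folds <- stratified_folds(yb, n_folds, fan_seed(seed, 100L))
  xall <- feature_matrix(tensor, candidates)
  gmap <- attr(xall, "groups")
  eval_set <- function(units) {
    cv_auc(xall[, gmap %in% units, drop = FALSE], yb, n_folds = n_folds,
           inverse_reg = inverse_reg, n_mad = n_mad, seed = seed,
           folds = folds)
  }
  selected <- character(0)
  best_auc <- 0.5
  best_cv <- NULL
  trace <- numeric(0)
  first_best <- NULL
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0 || length(selected) >= max_groups) break
    scores <- vapply(remaining, function(u)
      eval_set(c(selected, u))$mean_auc, 0)
    i <- which.max(scores)  # first max: ties by candidate order
    if (length(selected) == 0 && is.null(first_best))
      first_best <- remaining[i]
    if (scores[i] - best_auc >= min_gain) {
      selected <- c(selected, remaining[i])
      best_auc <- scores[i]
      best_cv <- eval_set(selected)
      trace <- c(trace, best_auc)
    } else break
  }
  if (length(selected) == 0) {
    cv <- eval_set(first_best)
    cv$empty_selection <- TRUE
    return(list(selected = character(0), cv = cv, trace = trace,
                best_rejected = first_best))
  }
  best_cv$empty_selection <- FALSE
  list(selected = selected, cv = best_cv, trace = trace)
}

#' Bootstrap confidence interval of the cross-validated AUC
#'
#' For a frozen feature selection, draws `n_boot` stratified resamples of
#' the trials with replacement (class counts preserved), reruns the full
#' leakage-safe 5-fold CV on each, and returns the percentile 95% CI of
#' the mean AUC. Degenerate resamples (a class collapsing to a single
#' value set that breaks folding) are redrawn and counted.
#'
#' @param x feature matrix restricted to the selected groups.
#' @param y labels or 0/1 outcome.
#' @param n_boot bootstrap resamples (1000).
#' @param n_folds,inverse_reg,n_mad,coding passed to [cv_auc()].
#' @param seed RNG seed.
#' @return list: `ci` (2.5/97.5 percentiles), `boot_aucs`, `n_redrawn`.
#' @export
bootstrap_auc <- function(x, y, n_boot = 1000, n_folds = 5,
                          inverse_reg = 1, n_mad = 3, seed = 1L,
                          coding = c("fast1", "slow1")) {
  coding <- match.arg(coding)
  x <- as.matrix(x)
  yb <- encode_outcome(y, coding)
  i0 <- which(yb == 0L)
  i1 <- which(yb == 1L)
  set.seed(fan_seed(seed, 7L))
  boot <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (draw in 1:20) {
      idx <- c(sample(i0, length(i0), replace = TRUE),
               sample(i1, length(i1), replace = TRUE))
      r <- try(cv_auc(x[idx, , drop = FALSE], yb[idx], n_folds = n_folds,
                      inverse_reg = inverse_reg,
                      n_mad = if (draw < 20) n_mad else Inf,
                      seed = fan_seed(seed, b)),
               silent = TRUE)
      if (!inherits(r, "try-error")) break
      redrawn <- redrawn + 1L
    }
    if (inherits(r, "try-error"))
      stop("bootstrap_auc: irrecoverably degenerate resample")
    boot[b] <- r$mean_auc
  }
  if (redrawn > 0L)
    message("bootstrap_auc: ", redrawn, " degenerate resample(s) redrawn")
  list(ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       boot_aucs = boot, n_redrawn = redrawn)
}

#' Assemble a subject's decoding result
#'
#' @param selection an [sfs_grouped()] result.
#' @param bootstrap a [bootstrap_auc()] result (or `NULL` when selection
#'   is empty).
#' @param subject subject label.
#' @return `subject_decoding_result`: selected groups, fold AUCs, mean
#'   AUC, delta AUC, bootstrap CI, mean standardized coefficient over
#'   folds and selected features, per-feature coefficients, above-chance
#'   flag (CI lower bound > 0.5).
#' @export
summarize_subject <- function(selection, bootstrap = NULL,
                              subject = "sub-01") {
  cv <- selection$cv
  sel <- selection$selected
  coefs <- cv$coefficients
  mean_coef <- if (length(sel) > 0) mean(coefs) else NA_real_
  ci <- if (!is.null(bootstrap)) bootstrap$ci else c(NA_real_, NA_real_)
  structure(list(
    subject = subject,
    selected_groups = sel,
    fold_aucs = cv$fold_aucs,
    mean_auc = cv$mean_auc,
    delta_auc = cv$mean_auc - 0.5,
    bootstrap_ci = ci,
    mean_coefficient = mean_coef,
    per_feature_coefficients = colMeans(coefs),
    above_chance = isTRUE(ci[1] > 0.5),
    empty_selection = isTRUE(cv$empty_selection)
  ), class = "subject_decoding_result")
}

#' Run the full decoding pipeline for one subject tensor
#'
#' SFS over the candidate groups, then bootstrap stability of the frozen
#' selection, then summary.
#'
#' @param tensor a [feature_tensor()].
#' @param candidates candidate unit ids (default: all units).
#' @param n_boot bootstrap resamples.
#' @param min_gain,max_groups,n_folds,inverse_reg,n_mad,coding,seed as in
#'   the component functions.
#' @param subject subject label.
#' @return a [summarize_subject()] result.
#' @export
decode_subject <- function(tensor, candidates = tensor$unit_ids,
                           n_boot = 1000, min_gain = 0.002, max_groups = 3,
                           n_folds = 5, inverse_reg = 1, n_mad = 3,
                           seed = 1L, coding = c("fast1", "slow1"),
                           subject = "sub-01") {
  coding <- match.arg(coding)
  sel <- sfs_grouped(tensor, candidates, min_gain = min_gain,
                     max_groups = max_groups, n_folds = n_folds,
                     inverse_reg = inverse_reg, n_mad = n_mad, seed = seed,
                     coding = coding)
  boot <- NULL
  if (length(sel$selected) > 0) {
    x <- feature_matrix(tensor, sel$selected)
    boot <- bootstrap_auc(x, tensor$labels, n_boot = n_boot,
                          n_folds = n_folds, inverse_reg = inverse_reg,
                          n_mad = n_mad, seed = seed, coding = coding)
  }
  summarize_subject(sel, boot, subject = subject)
}

#' Selection-frequency table over candidates
#'
#' Counts, over the above-chance subjects only, how often each candidate
#' group was selected.
#'
#' @param results list of `subject_decoding_result`.
#' @param candidates candidate unit ids.
#' @return data.frame `unit`, `count`, sorted decreasing.
#' @export
selection_frequency <- function(results, candidates) {
  ok <- Filter(function(r) r$above_chance, results)
  cnt <- table(factor(unlist(lapply(ok, `[[`, "selected_groups")),
                      levels = candidates))
  out <- data.frame(unit = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$unit), ]
}
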