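# Leakage correction and connectivity: symmetric orthogonalization of
# parcel time courses, and seed-based per-trial imaginary coherence.

#' Symmetric (closest-orthogonal) orthogonalization of parcel time courses
#'
#' Finds, per trial, the set of mutually orthogonal (zero-lag) time courses
#' closest in total squared change to the originals: the
#' closest-orthonormal-matrix solution with per-parcel magnitudes refit,
#' iterated to tolerance. Being symmetric, the result does not depend on
#' parcel order, unlike sequential Gram-Schmidt. Used to suppress zero-lag
#' signal leakage before coherence estimation.
#'
#' @param parcels real-valued [parcel_tc()].
#' @param tol relative convergence tolerance on the scale refit.
#' @param max_iter maximum iterations per trial.
#' @return list with `parcels` (orthogonalized [parcel_tc()]) and `report`
#'   (fields `max_abs_pairwise_zero_lag_correlation`, `frobenius_change`,
#'   `iterations`, `converged`).
#' @export
symmetric_orthogonalize <- function(parcels, tol = 1e-10, max_iter = 50) {
  stopifnot(inherits(parcels, "parcel_tc"))
  if (parcels$analytic)
    stop("symmetric_orthogonalize: apply to real-valued time courses")
  d <- dim(parcels$data)
  n_trials <- d[1]; p <- d[2]; n_samp <- d[3]
  if (p > n_samp)
    stop("symmetric_orthogonalize: more parcels than samples per trial")
  out <- parcels$data
  max_corr <- 0
  num2 <- 0; den2 <- 0
  iters <- 0L
  all_conv <- TRUE
  for (tr in seq_len(n_trials)) {
    X <- t(out[tr, , , drop = TRUE])
    if (p == 1L) X <- matrix(out[tr, 1, ], ncol = 1L)
    X <- sweep(X, 2, colMeans(X))
    sv <- svd(X, nu = 0, nv = 0)$d
    if (min(sv) < max(sv) * 1e-10) {
      cm <- abs(suppressWarnings(stats::cor(X)))
      diag(cm) <- 0
      bad <- which(cm > 1 - 1e-8, arr.ind = TRUE)
      off <- if (nrow(bad) > 0)
        paste(unique(parcels$parcel_names[sort(unique(as.vector(bad)))]),
              collapse = ", ")
      else "unidentified"
      stop("symmetric_orthogonalize: rank-deficient parcel matrix in trial ",
           tr, " (offending parcels: ", off, ")")
    }
    dvec <- sqrt(colSums(X^2))
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      s <- svd(X %*% diag(dvec, p, p))
      O <- s$u %*% t(s$v)
      dnew <- colSums(X * O)
      if (max(abs(dnew - dvec)) <= tol * max(abs(dnew))) {
        dvec <- dnew
        converged <- TRUE
        break
      }
      dvec <- dnew
      if (it >= max_iter) break
    }
    Y <- O %*% diag(dvec, p, p)
    cm <- abs(suppressWarnings(stats::cor(Y)))
    diag(cm) <- 0
    cm[!is.finite(cm)] <- 0
    max_corr <- max(max_corr, max(cm))
    num2 <- num2 + sum((Y - X)^2)
    den2 <- den2 + sum(X^2)
    iters <- max(iters, it)
    all_conv <- all_conv && converged
    out[tr, , ] <- t(Y)
  }
  res <- parcels
  res$data <- out
  list(
    parcels = res,
    report = list(
      max_abs_pairwise_zero_lag_correlation = max_corr,
      frobenius_change = sqrt(num2 / den2),
      iterations = iters,
      converged = all_conv
    )
  )
}

#' Per-trial, per-window imaginary coherence between two analytic signals
#'
#' Within each analysis window, the cross-spectrum is estimated as the
#' sample mean of `x * Conj(y)`; imaginary coherence is the magnitude of
#' the imaginary part of the normalized cross-spectrum,
#' `|Im(Sxy / sqrt(Sxx*Syy))|`, which lies in `[0,1]` by construction and
#' is insensitive to zero-lag (real) mixing. Windows where either signal
#' has zero power yield `NA` (flagged, excluded downstream).
#'
#' @param x,y complex matrices, trials x samples (analytic signals).
#' @param fs sampling rate, Hz.
#' @param t0 event-relative time of first sample, s.
#' @param grid [window_grid()].
#' @param min_window_samples smallest usable window length.
#' @return matrix trials x windows of iCoh values.
#' @export
compute_icoh <- function(x, y, fs, t0, grid = window_grid(),
                         min_window_samples = 16) {
  x <- rbind(x); y <- rbind(y)
  if (!all(dim(x) == dim(y)))
    stop("compute_icoh: x and y must have identical dimensions")
  if (!is.complex(x) || !is.complex(y))
    stop("compute_icoh: inputs must be complex analytic signals")
  n_samp <- ncol(x)
  widx <- apply(grid$windows, 1, function(w)
    window_index(n_samp, fs, t0, w), simplify = FALSE)
  ns <- vapply(widx, length, 0L)
  if (any(ns < min_window_samples))
    stop("compute_icoh: window sample count below ", min_window_samples)
  out <- matrix(NA_real_, nrow(x), length(widx))
  for (w in seq_along(widx)) {
    idx <- widx[[w]]
    Sxy <- rowMeans(x[, idx, drop = FALSE] * Conj(y[, idx, drop = FALSE]))
    Sxx <- rowMeans(Mod(x[, idx, drop = FALSE])^2)
    Syy <- rowMeans(Mod(y[, idx, drop = FALSE])^2)
    denom <- sqrt(Sxx * Syy)
    v <- abs(Im(Sxy / denom))
    v[denom == 0] <- NA_real_
    out[, w] <- v
  }
  out
}

#' Seed-based imaginary coherence tensor
#'
#' Applies [compute_icoh()] between the designated seed parcel and every
#' other parcel, yielding a trials x (parcels-1) x windows tensor.
#' Orthogonalization is expected to have been applied upstream.
#'
#' @param parcels analytic [parcel_tc()] with a designated seed.
#' @param grid [window_grid()].
#' @return a [feature_tensor()] with metric `"icoh"`, space `"source"`.
#' @export
seed_icoh_tensor <- function(parcels, grid = window_grid()) {
  stopifnot(inherits(parcels, "parcel_tc"))
  if (!parcels$analytic) stop("seed_icoh_tensor: input must be analytic")
  seed_idx <- match(parcels$seed_name, parcels$parcel_names)
  if (is.na(seed_idx)) stop("seed_icoh_tensor: seed parcel missing")
  d <- dim(parcels$data)
  others <- setdiff(seq_len(d[2]), seed_idx)
  X <- matrix(parcels$data[, seed_idx, ], d[1], d[3])
  out <- array(NA_real_, c(d[1], length(others), nrow(grid$windows)))
  for (j in seq_along(others)) {
    Y <- matrix(parcels$data[, others[j], ], d[1], d[3])
    out[, j, ] <- compute_icoh(X, Y, parcels$fs, parcels$t0, grid)
  }
  feature_tensor(out, parcels$parcel_names[others], "icoh", parcels$band,
                 parcels$labels, "source",
                 window_names = window_labels(grid$windows))
}
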