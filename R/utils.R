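# Internal numerical helpers: batched FFT filtering, analytic signals,
# seed fan-out, rank AUC, small hashes.

#' @keywords internal
#' @noRd
next_fast_len <- function(n) {
  # smallest 5-smooth integer >= n (FFT-friendly length)
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Zero-phase FIR filtering of matrix columns via FFT
#'
#' Applies the squared-magnitude frequency response of a linear-phase FIR
#' kernel, which equals forward-backward (`filtfilt`) filtering under
#' zero-padded edges: zero phase, doubled stop-band attenuation.
#'
#' @param x numeric matrix, samples x series.
#' @param kernel FIR impulse response.
#' @return filtered matrix, same dimensions as `x`.
#' @keywords internal
#' @noRd
fft_filtfilt_mat <- function(x, kernel) {
  x <- as.matrix(x)
  n <- nrow(x)
  L <- length(kernel)
  nfft <- next_fast_len(n + 2L * (L - 1L))
  H <- stats::fft(c(kernel, rep(0, nfft - L)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  # |H|^2 is the transfer function of kernel (*) time-reversed kernel:
  # zero-phase, zero net delay; padding absorbs the wrap-around tails
  Y <- Re(stats::mvfft(X * (Mod(H)^2), inverse = TRUE)) / nfft
  Y[seq_len(n), , drop = FALSE]
}

#' Analytic signal (Hilbert transform) of matrix columns
#' @keywords internal
#' @noRd
analytic_signal_mat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Deterministic child seed from a master seed
#'
#' Fans one master seed out to per-stage/per-subject seeds so that every
#' stochastic stage of a run is reproducible from a single integer.
#' Derived seeds stay in `[1, 2^31 - 2]`, the valid R integer seed range.
#'
#' @param master master seed (integer).
#' @param k child index.
#' @return an integer seed.
#' @export
fan_seed <- function(master, k) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(k) * 16807
  as.integer(s %% (m - 1)) + 1L
}

#' Rank-based AUC of scores against binary labels
#'
#' Mann-Whitney formulation; ties (e.g. constant scores) give 0.5.
#' @keywords internal
#' @noRd
auc_rank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc_rank: both classes required")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' FNV-1a hash of a character scalar, as 8 hex digits
#' @keywords internal
#' @noRd
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply split to stay within double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Canonical JSON hash of an R object (config provenance)
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  fnv1a(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' Raw median absolute deviation (no consistency constant)
#' @keywords internal
#' @noRd
mad_raw <- function(x) {
  stats::median(abs(x - stats::median(x, na.rm = TRUE)), na.rm = TRUE)
}

#' Column medians without per-column dispatch overhead
#' @keywords internal
#' @noRd
col_medians <- function(x) {
  n <- nrow(x)
  xs <- apply(x, 2, sort.int, method = "quick")
  if (n %% 2 == 1) xs[(n + 1) / 2, ]
  else (xs[n / 2, ] + xs[n / 2 + 1, ]) / 2
}
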