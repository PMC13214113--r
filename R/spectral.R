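# Spectral features: Morlet band power in sensor space, zero-phase FIR
# band filtering + decimation + Hilbert analytic signal in source space,
# window averaging and baseline dB correction.

#' Windowed-sinc FIR band-pass kernel
#'
#' Hamming-windowed sinc design via [signal::fir1()]. The order is chosen
#' from the transition width (classic ~3.3/transition rule for a Hamming
#' window), giving a stop-band attenuation of about 53 dB per pass; the
#' zero-phase two-pass application doubles that.
#'
#' @param band [band_def()].
#' @param fs sampling rate, Hz.
#' @param trans transition width, Hz.
#' @return numeric impulse response (odd length, linear phase).
#' @export
design_fir_bandpass <- function(band, fs, trans = 2) {
  if (fs < 2 * band$f_hi)
    stop("design_fir_bandpass: fs must be at least 2*f_hi")
  n <- ceiling(3.3 * fs / trans)
  if (n %% 2 == 1L) n <- n + 1L
  signal::fir1(n, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
}

#' Complex Morlet wavelet, discrete, unit L2 norm
#' @keywords internal
#' @noRd
morlet_kernel <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Sensor-space Morlet band power in analysis windows
#'
#' Convolves each epoch with complex Morlet wavelets at 1 Hz steps across
#' the band, takes per-frequency squared magnitude, averages across
#' frequencies, then averages within each analysis window.
#'
#' The per-frequency power-then-average order is the standard practice;
#' averaging the complex coefficients across frequencies before squaring
#' (which cancels phase) is available via `average_complex_first = TRUE`
#' for comparison.
#'
#' @param epochs an [epoch_set()].
#' @param band [band_def()].
#' @param grid [window_grid()] (its `windows` are used; pass
#'   `use_baseline_windows = TRUE` to average within the baseline windows
#'   instead, for baseline epochs).
#' @param n_cycles wavelet cycles per frequency.
#' @param f_step frequency step, Hz.
#' @param average_complex_first literal complex-average-then-square variant.
#' @param use_baseline_windows average within the 3 baseline windows.
#' @return a [feature_tensor()] with metric `"power"`, space `"sensor"`.
#' @export
morlet_band_power <- function(epochs, band, grid = window_grid(),
                              n_cycles = 7, f_step = 1,
                              average_complex_first = FALSE,
                              use_baseline_windows = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$fs < 2 * band$f_hi)
    stop("morlet_band_power: fs must be at least 2*f_hi")
  wins <- if (use_baseline_windows) grid$baseline_windows else grid$windows
  d <- dim(epochs$data)
  n_trials <- d[1]; n_chan <- d[2]; n_samp <- d[3]
  freqs <- seq(band$f_lo, band$f_hi, by = f_step)
  kernels <- lapply(freqs, morlet_kernel, fs = epochs$fs, n_cycles = n_cycles)
  max_half <- max(vapply(kernels, function(k) (length(k) - 1L) / 2L, 0))
  nfft <- next_fast_len(n_samp + 2L * max_half)
  # wavelet centred at lag zero, wrapped for circular convolution
  Hs <- lapply(kernels, function(k) {
    half <- (length(k) - 1L) / 2L
    kv <- complex(length.out = nfft)
    kv[1:(half + 1L)] <- k[(half + 1L):length(k)]
    kv[(nfft - half + 1L):nfft] <- k[1:half]
    stats::fft(kv)
  })
  widx <- apply(wins, 1, function(w)
    window_index(n_samp, epochs$fs, epochs$t0, w), simplify = FALSE)
  out <- array(NA_real_, c(n_trials, n_chan, nrow(wins)))
  for (ch in seq_len(n_chan)) {
    mat <- t(epochs$data[, ch, , drop = TRUE])
    if (n_trials == 1L) mat <- matrix(epochs$data[1, ch, ], ncol = 1L)
    X <- stats::mvfft(rbind(mat, matrix(0, nfft - n_samp, n_trials)))
    acc <- matrix(0, n_samp, n_trials)
    if (average_complex_first) {
      cacc <- matrix(0 + 0i, n_samp, n_trials)
      for (H in Hs) {
        co <- stats::mvfft(X * H, inverse = TRUE)[seq_len(n_samp), , drop = FALSE] / nfft
        cacc <- cacc + co
      }
      acc <- Mod(cacc / length(Hs))^2
    } else {
      for (H in Hs) {
        co <- stats::mvfft(X * H, inverse = TRUE)[seq_len(n_samp), , drop = FALSE] / nfft
        acc <- acc + Mod(co)^2
      }
      acc <- acc / length(Hs)
    }
    for (w in seq_along(widx))
      out[, ch, w] <- colMeans(acc[widx[[w]], , drop = FALSE])
  }
  feature_tensor(out, epochs$channel_ids, "power", band, epochs$labels,
                 "sensor", window_names = window_labels(wins))
}

#' Baseline dB correction of a power tensor
#'
#' The baseline tensor (3 pre-neurofeedback windows, pooled conditions) is
#' averaged over its trials and windows per unit, and each value of the
#' analysis tensor is expressed as `10*log10(power/baseline)`. The baseline
#' is time-invariant across the 7 analysis windows.
#'
#' @param power analysis [feature_tensor()] (metric `"power"`).
#' @param baseline_power baseline [feature_tensor()] over the same units.
#' @return a feature tensor of dB values (metric `"power_db"`).
#' @export
baseline_db <- function(power, baseline_power) {
  stopifnot(inherits(power, "feature_tensor"),
            inherits(baseline_power, "feature_tensor"))
  if (!identical(power$unit_ids, baseline_power$unit_ids))
    stop("baseline_db: unit_ids differ between tensors")
  base <- apply(baseline_power$values, 2, mean, na.rm = TRUE)
  if (any(!is.finite(base)) || any(base <= 0))
    stop("baseline_db: nonpositive or undefined baseline power")
  db <- 10 * log10(sweep(power$values, 2, base, "/"))
  out <- power
  out$values <- db
  out$metric <- "power_db"
  out
}

#' Zero-phase band filtering and decimation of parcel time courses
#'
#' Zero-phase FIR band-pass (forward-backward via FFT) and anti-aliased
#' decimation to `fs_out`. The band-pass itself anti-aliases for integer
#' decimation factors, since the upper band edge plus transition width
#' lies well below the decimated Nyquist frequency; non-integer factors
#' are handled by polyphase resampling with a message. The epoch must
#' extend at least 0.2 s beyond `trim` on each side (edge margin,
#' removed later by [hilbert_parcels()]).
#'
#' @param parcels real-valued [parcel_tc()].
#' @param band optional [band_def()] overriding `parcels$band`.
#' @param fs_out output sampling rate, Hz (128 by default).
#' @param trim event-relative span the downstream analysis will retain.
#' @param trans FIR transition width, Hz.
#' @return real-valued [parcel_tc()] at `fs_out`, margins still attached.
#' @export
band_filter <- function(parcels, band = NULL, fs_out = 128,
                        trim = c(-1.5, 1.5), trans = 2) {
  stopifnot(inherits(parcels, "parcel_tc"))
  if (parcels$analytic) stop("band_filter: input must be real-valued")
  if (is.null(band)) band <- parcels$band
  if (parcels$fs < 2 * band$f_hi)
    stop("band_filter: fs must be at least 2*f_hi")
  d <- dim(parcels$data)
  n_trials <- d[1]; n_parc <- d[2]; n_samp <- d[3]
  t_end <- parcels$t0 + (n_samp - 1L) / parcels$fs
  if (parcels$t0 > trim[1] - 0.2 + 1e-9 || t_end < trim[2] + 0.2 - 1e-9)
    stop(sprintf(paste0("band_filter: epoch [%.3f;%.3f] lacks the ",
                        "0.2 s edge margin around [%.2f;%.2f]"),
                 parcels$t0, t_end, trim[1], trim[2]))
  kern <- design_fir_bandpass(band, parcels$fs, trans = trans)
  q <- parcels$fs / fs_out
  integer_q <- abs(q - round(q)) < 1e-9
  if (!integer_q)
    message(sprintf("band_filter: fs %g is not an integer multiple of %g; using polyphase resampling",
                    parcels$fs, fs_out))
  filt_parcel <- function(p) {
    mat <- t(parcels$data[, p, , drop = TRUE])
    if (n_trials == 1L) mat <- matrix(parcels$data[1, p, ], ncol = 1L)
    fm <- fft_filtfilt_mat(mat, kern)
    if (integer_q) {
      fm[seq(1L, n_samp, by = round(q)), , drop = FALSE]
    } else {
      apply(fm, 2, function(col) signal::resample(col, fs_out, parcels$fs))
    }
  }
  first <- filt_parcel(1L)
  out <- array(NA_real_, c(n_trials, n_parc, nrow(first)))
  out[, 1L, ] <- t(first)
  if (n_parc > 1L) for (p in 2:n_parc) out[, p, ] <- t(filt_parcel(p))
  parcel_tc(out, fs_out, parcels$t0, parcels$parcel_names,
            parcels$seed_name, band, parcels$labels, analytic = FALSE)
}

#' Hilbert analytic signal of parcel time courses, with margin trim
#'
#' @param parcels real-valued [parcel_tc()] (band-filtered).
#' @param trim event-relative span retained, seconds.
#' @return analytic (complex) [parcel_tc()].
#' @export
hilbert_parcels <- function(parcels, trim = c(-1.5, 1.5)) {
  stopifnot(inherits(parcels, "parcel_tc"))
  if (parcels$analytic) stop("hilbert_parcels: input must be real-valued")
  d <- dim(parcels$data)
  t_ax <- parcels$t0 + (seq_len(d[3]) - 1L) / parcels$fs
  keep <- which(t_ax >= trim[1] - 1e-9 & t_ax <= trim[2] + 1e-9)
  if (length(keep) == 0) stop("hilbert_parcels: trim span outside epoch")
  out <- array(0 + 0i, c(d[1], d[2], length(keep)))
  for (p in seq_len(d[2])) {
    mat <- t(parcels$data[, p, , drop = TRUE])
    if (d[1] == 1L) mat <- matrix(parcels$data[1, p, ], ncol = 1L)
    out[, p, ] <- t(analytic_signal_mat(mat)[keep, , drop = FALSE])
  }
  parcel_tc(out, parcels$fs, t_ax[keep[1]], parcels$parcel_names,
            parcels$seed_name, parcels$band, parcels$labels, analytic = TRUE)
}

#' Band filtering, decimation and Hilbert transform in one step
#'
#' Composition of [band_filter()] and [hilbert_parcels()]; use the parts
#' directly when orthogonalization must sit between them.
#'
#' @inheritParams band_filter
#' @return analytic (complex) [parcel_tc()] at `fs_out`, trimmed to `trim`.
#' @export
band_filter_hilbert <- function(parcels, band = NULL, fs_out = 128,
                                trim = c(-1.5, 1.5), trans = 2) {
  hilbert_parcels(band_filter(parcels, band, fs_out, trim, trans), trim)
}

#' Windowed power of analytic parcel signals
#'
#' Squared modulus of the analytic signal averaged within each analysis
#' window.
#'
#' @param parcels analytic [parcel_tc()].
#' @param grid [window_grid()].
#' @return a [feature_tensor()] with metric `"power"`, space `"source"`.
#' @export
analytic_power <- function(parcels, grid = window_grid()) {
  stopifnot(inherits(parcels, "parcel_tc"))
  if (!parcels$analytic) stop("analytic_power: input must be analytic")
  d <- dim(parcels$data)
  widx <- apply(grid$windows, 1, function(w)
    window_index(d[3], parcels$fs, parcels$t0, w), simplify = FALSE)
  out <- array(NA_real_, c(d[1], d[2], length(widx)))
  pw <- Mod(parcels$data)^2
  for (w in seq_along(widx))
    out[, , w] <- apply(pw[, , widx[[w]], drop = FALSE], c(1, 2), mean)
  feature_tensor(out, parcels$parcel_names, "power", parcels$band,
                 parcels$labels, "source",
                 window_names = window_labels(grid$windows))
}
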