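# Domain containers: band definitions, window grids, epoch sets, parcel
# time courses, feature tensors, kinematic traces. Plain S3 lists with
# validated constructors, following the trials x units x samples layout.

#' Define a frequency band
#'
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi`.
#' @return an object of class `band_def`.
#' @export
#' @examples
#' band_def("standard", 15, 25)
band_def <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo < f_hi))
    stop("band_def: need f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_def")
}

#' Beta sub-band presets
#'
#' The three beta sub-bands used throughout: low (8-15 Hz),
#' standard (15-25 Hz), high (25-35 Hz).
#'
#' @param name one of `"low"`, `"standard"`, `"high"`.
#' @return a [band_def()].
#' @export
beta_band <- function(name = c("standard", "low", "high")) {
  name <- match.arg(name)
  switch(name,
    low      = band_def("low", 8, 15),
    standard = band_def("standard", 15, 25),
    high     = band_def("high", 25, 35)
  )
}

#' Analysis and baseline window grid
#'
#' Seven 0.5 s analysis windows centred on the go cue with 50% overlap,
#' and the three 0.5 s baseline windows preceding neurofeedback onset.
#' Times are seconds relative to the respective event.
#'
#' @return list with matrices `windows` (7 x 2) and `baseline_windows`
#'   (3 x 2); columns are start and end.
#' @export
window_grid <- function() {
  w <- rbind(
    c(-1.00, -0.50), c(-0.75, -0.25), c(-0.50, 0.00), c(-0.25, 0.25),
    c(0.00, 0.50), c(0.25, 0.75), c(0.50, 1.00)
  )
  b <- rbind(c(-1.50, -1.00), c(-0.75, -0.25), c(-0.50, 0.00))
  colnames(w) <- colnames(b) <- c("start", "end")
  structure(list(windows = w, baseline_windows = b), class = "window_grid")
}

window_labels <- function(win) {
  sprintf("[%.2f;%.2f]", win[, 1], win[, 2])
}

#' Sample indices of a time window on an epoch time axis
#' @keywords internal
#' @noRd
window_index <- function(n_samples, fs, t0, win) {
  t <- t0 + (seq_len(n_samples) - 1L) / fs
  idx <- which(t >= win[1] - 1e-9 & t < win[2] - 1e-9)
  if (length(idx) == 0L ||
      win[1] < t[1] - 1e-9 || win[2] > t[n_samples] + 1 / fs + 1e-9)
    stop(sprintf("window [%.2f;%.2f] outside epoch span [%.3f;%.3f]",
                 win[1], win[2], t[1], t[n_samples]))
  idx
}

#' Epoched multichannel sensor data
#'
#' @param data trials x channels x samples numeric array.
#' @param fs sampling rate, Hz.
#' @param t0 event-relative time of the first sample, seconds.
#' @param labels per-trial condition, `"Fast"`/`"Slow"`.
#' @param channel_ids channel labels.
#' @param positions channels x 2 matrix of 2-D montage coordinates.
#' @param subject_id subject label.
#' @return an `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, labels, channel_ids, positions,
                      subject_id = "sub-01") {
  stopifnot(length(dim(data)) == 3L)
  if (length(labels) != dim(data)[1])
    stop("epoch_set: labels length must equal trial count")
  if (length(channel_ids) != dim(data)[2])
    stop("epoch_set: channel_ids length must equal channel count")
  positions <- as.matrix(positions)
  if (nrow(positions) != dim(data)[2] || ncol(positions) != 2L)
    stop("epoch_set: positions must be channels x 2")
  structure(list(
    data = data, fs = fs, t0 = t0, labels = as.character(labels),
    channel_ids = as.character(channel_ids), positions = positions,
    subject_id = subject_id
  ), class = "epoch_set")
}

#' Parcel-level time courses
#'
#' @param data trials x parcels x samples array; real-valued before the
#'   Hilbert step, complex analytic afterwards.
#' @param fs sampling rate, Hz.
#' @param t0 event-relative time of the first sample, seconds.
#' @param parcel_names parcel labels (atlas naming).
#' @param seed_name designated seed parcel; must be in `parcel_names`.
#' @param band [band_def()] the data is (to be) filtered in.
#' @param labels per-trial condition.
#' @param analytic logical, complex analytic data?
#' @return a `parcel_tc`.
#' @export
parcel_tc <- function(data, fs, t0, parcel_names, seed_name, band, labels,
                      analytic = FALSE) {
  stopifnot(length(dim(data)) == 3L)
  if (length(parcel_names) != dim(data)[2])
    stop("parcel_tc: parcel_names length must equal parcel count")
  if (!seed_name %in% parcel_names)
    stop("parcel_tc: seed parcel '", seed_name, "' not among parcel_names")
  if (length(labels) != dim(data)[1])
    stop("parcel_tc: labels length must equal trial count")
  if (analytic && !is.complex(data))
    stop("parcel_tc: analytic data must be complex-valued")
  structure(list(
    data = data, fs = fs, t0 = t0, parcel_names = as.character(parcel_names),
    seed_name = seed_name, band = band, labels = as.character(labels),
    analytic = isTRUE(analytic)
  ), class = "parcel_tc")
}

#' Windowed feature tensor (power or imaginary coherence)
#'
#' @param values trials x units x windows array.
#' @param unit_ids channel or parcel labels.
#' @param metric `"power"` or `"icoh"`.
#' @param band [band_def()].
#' @param labels per-trial condition.
#' @param space `"sensor"` or `"source"`.
#' @param window_names optional window labels.
#' @return a `feature_tensor`.
#' @export
feature_tensor <- function(values, unit_ids, metric = c("power", "icoh"),
                           band, labels, space = c("sensor", "source"),
                           window_names = NULL) {
  metric <- match.arg(metric)
  space <- match.arg(space)
  stopifnot(length(dim(values)) == 3L)
  if (length(unit_ids) != dim(values)[2])
    stop("feature_tensor: unit_ids length must equal unit count")
  if (length(labels) != dim(values)[1])
    stop("feature_tensor: labels length must equal trial count")
  if (metric == "icoh") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("feature_tensor: icoh values must lie in [0,1]")
  }
  if (metric == "power" && min(values, na.rm = TRUE) < -1e-12)
    stop("feature_tensor: power values must be nonnegative")
  dimnames(values) <- list(NULL, unit_ids, window_names)
  structure(list(
    values = values, unit_ids = as.character(unit_ids), metric = metric,
    band = band, labels = as.character(labels), space = space
  ), class = "feature_tensor")
}

#' Per-trial kinematic traces
#'
#' @param lux list of per-trial luminosity series (arbitrary units).
#' @param acc list of per-trial acceleration series (arbitrary units).
#' @param fs_behav behavioral sampling rate, Hz.
#' @param go_cue_index integer go-cue sample index per trial.
#' @param labels per-trial condition.
#' @return a `kinematic_traces`.
#' @export
kinematic_traces <- function(lux, acc, fs_behav, go_cue_index, labels) {
  if (length(lux) != length(acc))
    stop("kinematic_traces: lux and acc must have the same trial count")
  n <- length(lux)
  if (length(go_cue_index) != n || length(labels) != n)
    stop("kinematic_traces: go_cue_index and labels must match trial count")
  for (i in seq_len(n)) {
    if (go_cue_index[i] < 1L || go_cue_index[i] > length(lux[[i]]))
      stop("kinematic_traces: go_cue_index out of bounds for trial ", i)
  }
  structure(list(
    lux = lux, acc = acc, fs_behav = fs_behav,
    go_cue_index = as.integer(go_cue_index), labels = as.character(labels)
  ), class = "kinematic_traces")
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band_def> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %g Hz, t0=%.3f s\n",
              x$subject_id, d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' @export
print.parcel_tc <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<parcel_tc> %d trials x %d parcels x %d samples @ %g Hz, band %s, seed %s%s\n",
              d[1], d[2], d[3], x$fs, x$band$name, x$seed_name,
              if (x$analytic) " (analytic)" else ""))
  invisible(x)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %s/%s: %d trials x %d units x %d windows, band %s\n",
              x$space, x$metric, d[1], d[2], d[3], x$band$name))
  invisible(x)
}
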