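# Spectral features: window bookkeeping, Morlet band power, baseline dB,
# filter-Hilbert path, analytic power.

make_epochs <- function(signal_fun, n_trials = 2, fs = 512,
                        span = c(-1.7, 1.7), n_chan = 1) {
  n <- round(diff(span) * fs) + 1
  t <- span[1] + (seq_len(n) - 1) / fs
  data <- array(0, c(n_trials, n_chan, n))
  for (tr in seq_len(n_trials)) for (ch in seq_len(n_chan))
    data[tr, ch, ] <- signal_fun(t)
  epoch_set(data, fs, span[1], rep(c("Fast", "Slow"), length.out = n_trials),
            paste0("ch", seq_len(n_chan)),
            cbind(seq_len(n_chan) * 0.01, 0))
}

test_that("window grid is exactly the published layout", {
  g <- window_grid()
  expect_equal(g$windows[, 1], c(-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5))
  expect_equal(g$windows[, 2] - g$windows[, 1], rep(0.5, 7))
  expect_equal(g$baseline_windows,
               rbind(c(-1.5, -1), c(-0.75, -0.25), c(-0.5, 0)),
               ignore_attr = TRUE)
  # each window holds round(0.5*fs) samples; neighbours share half
  fs <- 128
  idx <- apply(g$windows, 1, function(w)
    betavigor:::window_index(385, fs, -1.5, w), simplify = FALSE)
  expect_true(all(vapply(idx, length, 0L) == 64))
  expect_length(intersect(idx[[1]], idx[[2]]), 32)
})

test_that("Morlet band power concentrates in the right band (FFT oracle)", {
  ep <- make_epochs(function(t) sin(2 * pi * 20 * t))
  p_std <- morlet_band_power(ep, beta_band("standard"))
  p_high <- morlet_band_power(ep, beta_band("high"))
  expect_gte(min(p_std$values / p_high$values), 10)
  # FFT oracle: the trace's spectral energy ratio between the two bands
  x <- ep$data[1, 1, ]
  pw <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * ep$fs / length(x)
  e_std <- sum(pw[f >= 15 & f <= 25])
  e_high <- sum(pw[f >= 25 & f <= 35])
  expect_gte(e_std / e_high, 10)

  expect_equal(max(abs(morlet_band_power(
    make_epochs(function(t) 0 * t), beta_band("standard"))$values)), 0)

  ep2 <- make_epochs(function(t) 2 * sin(2 * pi * 20 * t))
  p2 <- morlet_band_power(ep2, beta_band("standard"))
  expect_equal(p2$values / p_std$values, array(4, dim(p2$values)),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("windows outside the epoch are rejected by name", {
  ep <- make_epochs(function(t) sin(2 * pi * 20 * t), span = c(-1.2, 1.2))
  expect_error(
    betavigor:::window_index(dim(ep$data)[3], ep$fs, ep$t0, c(-1.5, -1.0)),
    "\\[-1.50;-1.00\\] outside epoch span")
})

test_that("baseline dB correction follows the log identity", {
  vals <- array(2, c(4, 3, 7))
  base <- array(1, c(8, 3, 3))
  mk <- function(v, nw) feature_tensor(v, paste0("u", 1:3), "power",
                                       beta_band("standard"),
                                       rep(c("Fast", "Slow"),
                                           length.out = dim(v)[1]), "sensor")
  p <- mk(vals); b <- mk(base)
  db <- baseline_db(p, b)
  expect_equal(db$values, array(10 * log10(2), c(4, 3, 7)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(db$values[1, 1, 1]), 3.0103, tolerance = 1e-4)
  expect_equal(unname(baseline_db(mk(base[1:4, , ]), b)$values[1, 1, 1]), 0)
  expect_equal(unname(baseline_db(mk(array(0.1, c(4, 3, 7))),
                                  b)$values[2, 2, 3]), -10)
  bad <- b; bad$values[, 2, ] <- 0
  expect_error(baseline_db(p, bad), "nonpositive")
})

test_that("filter-Hilbert path: passband envelope, stopband, decimation", {
  cfg_fs <- 512
  n <- round(3.4 * cfg_fs) + 1
  t <- -1.7 + (seq_len(n) - 1) / cfg_fs
  mk <- function(x) parcel_tc(array(rep(x, each = 2), c(2, 1, n)), cfg_fs,
                              -1.7, "p1", "p1", beta_band("standard"),
                              c("Fast", "Slow"))
  # 20 Hz in-band: analytic envelope constant within 2% away from edges
  an <- band_filter_hilbert(mk(sin(2 * pi * 20 * t)))
  env <- Mod(an$data[1, 1, ])
  t_dec <- an$t0 + (seq_along(env) - 1) / an$fs
  core <- env[t_dec > -1.2 & t_dec < 1.2]
  expect_lt((max(core) - min(core)) / mean(core), 0.02)
  expect_equal(an$fs, 128)

  # 40 Hz out-of-band: RMS < 5% of input RMS
  an40 <- band_filter_hilbert(mk(sin(2 * pi * 40 * t)))
  expect_lt(stats::sd(Re(an40$data[1, 1, ])) / stats::sd(sin(2 * pi * 40 * t)),
            0.05)

  # zero-phase: impulse response symmetric around the impulse
  imp <- rep(0, n); imp[(n + 1) / 2] <- 1
  ft <- band_filter(mk(imp), fs_out = cfg_fs)  # no decimation
  y <- ft$data[1, 1, ]
  ctr <- (n + 1) / 2
  expect_lt(max(abs(y[ctr + 1:300] - y[ctr - 1:300])), 1e-12)

  # decimation preserves in-band RMS within 2%
  x20 <- sin(2 * pi * 20 * t)
  full <- band_filter(mk(x20), fs_out = cfg_fs)
  dec <- band_filter(mk(x20))
  expect_equal(stats::sd(dec$data[1, 1, ]), stats::sd(full$data[1, 1, ]),
               tolerance = 0.02)

  # insufficient edge margin is rejected
  short <- parcel_tc(array(0, c(1, 1, 200)), 512, -1.55, "p1", "p1",
                     beta_band("standard"), "Fast")
  expect_error(band_filter(short), "edge margin")
})

test_that("analytic power averages |a|^2 per window", {
  fs <- 128
  n <- 385  # [-1.5, 1.5]
  t <- -1.5 + (seq_len(n) - 1) / fs
  # unit envelope
  a1 <- exp(2i * pi * 20 * t)
  tc1 <- make_analytic_tc(array(rep(a1, each = 1), c(1, 1, n)), fs = fs)
  p1 <- analytic_power(tc1)
  expect_equal(as.vector(p1$values), rep(1, 7), tolerance = 1e-12)

  # envelope step 1 -> 2 at the centre of window 4 ([-0.25, 0.25])
  env <- ifelse(t < 0, 1, 2)
  tc2 <- make_analytic_tc(array(env * a1, c(1, 1, n)), fs = fs)
  p2 <- analytic_power(tc2)
  expect_equal(p2$values[1, 1, 4], mean(ifelse(t[t >= -0.25 & t < 0.25] < 0, 1, 4)),
               tolerance = 1e-12)
  expect_equal(p2$values[1, 1, 4], 2.5, tolerance = 0.04)

  expect_equal(max(abs(analytic_power(
    make_analytic_tc(array(0i, c(1, 1, n)), fs = fs))$values)), 0)
  real_tc <- parcel_tc(array(1, c(1, 1, n)), fs, -1.5, "p1", "p1",
                       beta_band("standard"), "Fast")
  expect_error(analytic_power(real_tc), "must be analytic")
})

test_that("power is scale-equivariant on both paths", {
  ep <- make_epochs(function(t) sin(2 * pi * 18 * t) + 0.3 * rnorm(length(t)))
  p1 <- morlet_band_power(ep, beta_band("standard"))
  ep3 <- ep; ep3$data <- 3 * ep$data
  p3 <- morlet_band_power(ep3, beta_band("standard"))
  expect_equal(p3$values, 9 * p1$values, tolerance = 1e-10)
})
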