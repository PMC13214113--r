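# Shared fixtures: small configs, constructed traces/tensors, and a
# memoized default-conditions cohort run reused by the acceptance blocks.

tiny_cfg <- function(rng_seed = 7, ...) {
  sim_config(n_subjects = 2, n_trials_per_condition = 8,
             rng_seed = rng_seed, ...)
}

# a lux trace with rectified-Gaussian bumps at given times (s)
make_lux <- function(peak_times, fs = 100, duration = 4, base = 0.2,
                     height = 1.0, width = 0.05) {
  t <- seq(0, duration, by = 1 / fs)
  l <- rep(base, length(t))
  for (pk in peak_times) l <- l + (height - base) * exp(-(t - pk)^2 / (2 * width^2))
  l
}

# analytic parcel_tc wrapper around complex trial x parcel x sample data
make_analytic_tc <- function(data, fs = 128, t0 = -1.5,
                             parcel_names = NULL, seed_name = NULL,
                             labels = NULL) {
  d <- dim(data)
  if (is.null(parcel_names)) parcel_names <- paste0("p", seq_len(d[2]))
  if (is.null(seed_name)) seed_name <- parcel_names[1]
  if (is.null(labels)) labels <- rep(c("Fast", "Slow"), length.out = d[1])
  parcel_tc(data, fs, t0, parcel_names, seed_name, beta_band("standard"),
            labels, analytic = TRUE)
}

# narrowband analytic signals: unit-modulus complex with random walk phase
nb_analytic <- function(n_trials, n_samp, fs = 128, f0 = 20, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_samp) - 1) / fs
  out <- matrix(0 + 0i, n_trials, n_samp)
  for (tr in seq_len(n_trials)) {
    x <- stats::rnorm(n_samp)
    xf <- stats::fft(x)
    f <- seq(0, fs - fs / n_samp, by = fs / n_samp)
    keep <- f >= 15 & f <= 25
    xf[!keep] <- 0
    out[tr, ] <- stats::fft(xf, inverse = TRUE) / n_samp
  }
  out
}

# memoized heavy fixtures (shared across acceptance blocks)
.fixture_env <- new.env(parent = emptyenv())

default_cohort_run <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  cfg <- sim_config(rng_seed = 20260922)  # 12 subjects, 60 trials/cond
  cohort <- simulate_cohort(cfg)
  rc <- run_config(n_boot = 200, n_perm = 500, seed = 20260922)
  rep <- suppressMessages(suppressWarnings(run_end_to_end(cohort, rc)))
  .fixture_env$run <- list(config = cfg, cohort_truth = cohort$truth,
                           report = rep)
  .fixture_env$run
}
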