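# Synthetic multi-subject cohort generator. Plants, with configurable
# strength: (i) seed-parcel beta coupling that is stronger in Slow than
# Fast trials (trial-level imaginary-coherence effect), (ii) per-subject
# Fast-Slow seed power offsets of random sign, (iii) RT/MT shorter in Fast,
# with the across-subject association between the planted coherence effect
# and the Slow-Fast RT+MT difference controlled by a Gaussian copula.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: 12 subjects, 60 trials per
#' condition, a kappa contrast of 0.6 (0.8 Slow vs 0.2 Fast coupling), the
#' left precentral seed plus the 21 fronto-parietal parcels, and a
#' coefficient-scale behavioral correlation of -0.6.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_condition trials per condition (balanced by design).
#' @param fs acquisition sampling rate, Hz.
#' @param epoch_span event-relative epoch span, seconds; must contain
#'   `[-1.7, +1.7]` so the analysis windows plus the 0.2 s filter-trim
#'   margin are coverable.
#' @param band [band_def()] carrying the planted coupling (oscillatory
#'   content of the generated parcels).
#' @param seed_parcel seed parcel name.
#' @param parcel_names full parcel set (must contain seed and coupled).
#' @param coupled_parcels parcels receiving the seed coupling.
#' @param kappa_slow,kappa_fast coupling weights in `[0,1]`; the planted
#'   coherence contrast is `kappa_slow - kappa_fast` (equal values give a
#'   null cohort).
#' @param kappa_sd between-subject spread of the coupling contrast.
#' @param coupling_phase phase lag of the coupling, radians; the default
#'   quarter cycle maximises imaginary coherence.
#' @param power_effect_sd dB-scale spread of per-subject Fast-Slow seed
#'   power offsets, centred at 0 (random sign across subjects).
#' @param rt_ms,mt_ms named lists `list(Fast=c(mean,sd), Slow=c(mean,sd))`
#'   of per-condition reaction/movement time, milliseconds.
#' @param behavior_diff_sd between-subject sd of the Slow-Fast RT+MT
#'   difference, seconds.
#' @param rho_behavior target across-subject correlation between the
#'   planted coherence effect (on the Fast-minus-Slow, i.e. coefficient,
#'   scale) and the Slow-Fast RT+MT difference.
#' @param noise_1f_exponent spectral exponent of the sensor noise.
#' @param parcel_noise_sd sd of the broadband floor added to each parcel.
#' @param sensor_noise_sd sd of the 1/f sensor noise.
#' @param n_channels channel count of the synthetic montage (max 32).
#' @param fs_behav behavioral sampling rate, Hz.
#' @param rng_seed master seed; identical seeds give bit-identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 12,
                       n_trials_per_condition = 60,
                       fs = 512,
                       epoch_span = c(-1.7, 1.7),
                       band = beta_band("standard"),
                       seed_parcel = "precentral-lh",
                       parcel_names = c("precentral-lh",
                                        dk_frontoparietal_parcels()),
                       coupled_parcels = c("precuneus-rh", "precuneus-lh",
                                           "superiorparietal-rh",
                                           "postcentral-lh"),
                       kappa_slow = 0.8,
                       kappa_fast = 0.2,
                       kappa_sd = 0.15,
                       coupling_phase = pi / 2,
                       power_effect_sd = 1.5,
                       rt_ms = list(Fast = c(mean = 350, sd = 60),
                                    Slow = c(mean = 500, sd = 90)),
                       mt_ms = list(Fast = c(mean = 250, sd = 50),
                                    Slow = c(mean = 600, sd = 120)),
                       behavior_diff_sd = 0.15,
                       rho_behavior = -0.6,
                       noise_1f_exponent = 1.0,
                       parcel_noise_sd = 0.1,
                       sensor_noise_sd = 0.5,
                       n_channels = 32,
                       fs_behav = 100,
                       rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    fs = fs, epoch_span = epoch_span, band = band,
    seed_parcel = seed_parcel, parcel_names = parcel_names,
    coupled_parcels = coupled_parcels,
    kappa_slow = kappa_slow, kappa_fast = kappa_fast, kappa_sd = kappa_sd,
    coupling_phase = coupling_phase, power_effect_sd = power_effect_sd,
    rt_ms = rt_ms, mt_ms = mt_ms, behavior_diff_sd = behavior_diff_sd,
    rho_behavior = rho_behavior, noise_1f_exponent = noise_1f_exponent,
    parcel_noise_sd = parcel_noise_sd, sensor_noise_sd = sensor_noise_sd,
    n_channels = as.integer(n_channels), fs_behav = fs_behav,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!(cfg$kappa_fast >= 0 && cfg$kappa_slow <= 1 &&
        cfg$kappa_fast <= cfg$kappa_slow))
    stop("sim_config: need 0 <= kappa_fast <= kappa_slow <= 1")
  if (cfg$epoch_span[1] > -1.7 + 1e-9 || cfg$epoch_span[2] < 1.7 - 1e-9)
    stop("sim_config: epoch_span too short for the analysis windows ",
         "[-1.5,1.5] plus the 0.2 s trim margin; need it to contain [-1.7,1.7]")
  if (cfg$n_trials_per_condition < 5L)
    stop("sim_config: n_trials_per_condition must be at least the fold count (5)")
  if (!cfg$seed_parcel %in% cfg$parcel_names)
    stop("sim_config: seed_parcel must be among parcel_names")
  if (!all(cfg$coupled_parcels %in% cfg$parcel_names))
    stop("sim_config: coupled_parcels must be among parcel_names")
  if (cfg$seed_parcel %in% cfg$coupled_parcels)
    stop("sim_config: seed parcel cannot be coupled to itself")
  if (cfg$n_channels > 32L || cfg$n_channels < 4L)
    stop("sim_config: n_channels must be between 4 and 32")
  invisible(cfg)
}

#' Subject-level planted quantities (the cohort's true-effect record)
#'
#' Draws, from the master seed alone, each subject's coupling weights,
#' power offset and target behavioral difference. The Gaussian copula
#' correlates the planted coherence effect (Fast-minus-Slow scale) with
#' the Slow-Fast RT+MT difference at `rho_behavior`. A zero planted
#' contrast (`kappa_slow == kappa_fast`) propagates exactly: the cohort is
#' null, with no between-subject coupling spread.
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per subject.
#' @export
subject_latents <- function(config) {
  set.seed(fan_seed(config$rng_seed, 0L))
  n <- config$n_subjects
  contrast_mean <- config$kappa_slow - config$kappa_fast
  mid <- (config$kappa_slow + config$kappa_fast) / 2
  rho_lat <- -config$rho_behavior  # effect is -(contrast): see below
  z1 <- stats::rnorm(n)
  z2 <- rho_lat * z1 + sqrt(max(0, 1 - rho_lat^2)) * stats::rnorm(n)
  if (contrast_mean == 0) {
    contrast <- rep(0, n)
  } else {
    cmax <- 2 * min(mid, 1 - mid)
    contrast <- pmin(pmax(contrast_mean + config$kappa_sd * z1, 0), cmax)
  }
  rt <- config$rt_ms; mt <- config$mt_ms
  diff_mean <- (rt$Slow[["mean"]] + mt$Slow[["mean"]] -
                rt$Fast[["mean"]] - mt$Fast[["mean"]]) / 1000
  diff_target <- diff_mean + config$behavior_diff_sd * z2
  data.frame(
    subject = sprintf("sub-%02d", seq_len(n)),
    kappa_slow = mid + contrast / 2,
    kappa_fast = mid - contrast / 2,
    coherence_effect = -contrast,     # Fast - Slow directional modulation
    power_offset_db = stats::rnorm(n, 0, config$power_effect_sd),
    behavior_diff_target = diff_target,
    stringsAsFactors = FALSE
  )
}

#' Band-limited unit-variance Gaussian noise matrix (samples x series)
#'
#' Direct frequency-domain synthesis: complex Gaussian spectrum inside
#' the band, zero outside, real part of the inverse FFT.
#' @keywords internal
#' @noRd
band_noise_mat <- function(n, m, fs, band) {
  nfft <- next_fast_len(n)
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- which(f >= band$f_lo & f <= band$f_hi & f <= fs / 2)
  spec <- matrix(0 + 0i, nfft, m)
  nk <- length(keep)
  spec[keep, ] <- complex(real = stats::rnorm(nk * m),
                          imaginary = stats::rnorm(nk * m))
  X <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  sweep(X, 2, apply(X, 2, stats::sd), "/")
}

#' 1/f noise matrix (samples x series)
#' @keywords internal
#' @noRd
pink_noise_mat <- function(n, m, fs, exponent, sd = 1) {
  nfft <- next_fast_len(n)
  f <- c(1, seq_len(nfft - 1))  # avoid f=0
  f <- pmin(f, nfft - f + 1) * fs / nfft
  amp <- f^(-exponent / 2)
  W <- stats::mvfft(matrix(stats::rnorm(nfft * m), nfft, m))
  X <- Re(stats::mvfft(W * amp, inverse = TRUE)) / nfft
  X <- X[seq_len(n), , drop = FALSE]
  X <- sweep(X, 2, apply(X, 2, stats::sd), "/") * sd
  X
}

#' Simulate one subject of the synthetic cohort
#'
#' @param config a [sim_config()].
#' @param s subject index.
#' @param latents the [subject_latents()] table (drawn once per cohort).
#' @param include_sensor also generate the mixed sensor epochs (skipping
#'   them saves time and memory when only the source path is needed).
#' @return list with `epochs` (or `NULL`), `parcels` (real [parcel_tc()]
#'   at the acquisition rate), `kinematics`, and `trials` (per-trial truth).
#' @export
simulate_subject <- function(config, s, latents = subject_latents(config),
                             include_sensor = TRUE) {
  set.seed(fan_seed(config$rng_seed, s))
  lat <- latents[s, ]
  n_cond <- config$n_trials_per_condition
  n_trials <- 2L * n_cond
  labels <- sample(rep(c("Fast", "Slow"), each = n_cond))
  fs <- config$fs
  n_samp <- round((config$epoch_span[2] - config$epoch_span[1]) * fs) + 1L
  t0 <- config$epoch_span[1]
  parcels <- config$parcel_names
  p <- length(parcels)
  seed_i <- match(config$seed_parcel, parcels)
  coup_i <- match(config$coupled_parcels, parcels)

  # band-limited unit-variance carriers: one per parcel per trial
  C <- band_noise_mat(n_samp, n_trials * p, fs, config$band)
  # quarter-cycle (coupling_phase) shifted copy of each trial's seed carrier
  seed_cols <- (seq_len(n_trials) - 1L) * p + seed_i
  shifted <- Re(analytic_signal_mat(C[, seed_cols, drop = FALSE]) *
                  exp(1i * config$coupling_phase))
  pink <- pink_noise_mat(n_samp, n_trials * p, fs, config$noise_1f_exponent,
                         sd = config$parcel_noise_sd)
  g_fast <- 10^(lat$power_offset_db / 20)
  kap <- ifelse(labels == "Fast", lat$kappa_fast, lat$kappa_slow)
  pdat <- array(NA_real_, c(n_trials, p, n_samp))
  for (tr in seq_len(n_trials)) {
    cols <- (tr - 1L) * p + seq_len(p)
    M <- C[, cols, drop = FALSE]
    M[, coup_i] <- kap[tr] * shifted[, tr] +
      (1 - kap[tr]) * M[, coup_i, drop = FALSE]
    if (labels[tr] == "Fast") M[, seed_i] <- g_fast * M[, seed_i]
    M <- M + pink[, cols, drop = FALSE]
    pdat[tr, , ] <- t(M)
  }
  ptc <- parcel_tc(pdat, fs, t0, parcels, config$seed_parcel, config$band,
                   labels, analytic = FALSE)

  epochs <- NULL
  if (include_sensor) {
    mont <- default_montage()
    keep <- seq_len(config$n_channels)
    chan_ids <- mont$channel_ids[keep]
    pos <- mont$positions[keep, , drop = FALSE]
    # Gaussian leadfield-like mixing: each parcel anchored near a channel.
    # Coupled parcels are anchored at mutually distant channels so that no
    # channel pools two coupled parcels: their shared carrier would
    # otherwise turn the condition-dependent inter-parcel covariance into
    # a spurious sensor-power contrast.
    anchor_ch <- ((seq_len(p) * 7L) %% length(keep)) + 1L
    anchor_ch[seed_i] <- match("D19", chan_ids)
    corner_dist <- lapply(list(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1)),
                          function(cn)
                            (pos[, 1] - cn[1] * 0.05)^2 +
                            (pos[, 2] - cn[2] * 0.05)^2)
    for (k in seq_along(coup_i)) {
      corner <- corner_dist[[((k - 1L) %% 4L) + 1L]]
      free <- setdiff(order(corner), anchor_ch[c(seed_i, coup_i[seq_len(k - 1L)])])
      anchor_ch[coup_i[k]] <- free[1L]
    }
    loc <- pos[anchor_ch, , drop = FALSE] +
      matrix(stats::rnorm(2 * p, 0, 0.002), p, 2)
    d2 <- outer(pos[, 1], loc[, 1], "-")^2 + outer(pos[, 2], loc[, 2], "-")^2
    Mix <- exp(-d2 / (2 * 0.010^2)) + matrix(stats::rnorm(nrow(pos) * p, 0, 1e-3),
                                             nrow(pos), p)
    snoise <- pink_noise_mat(n_samp, n_trials * length(keep), fs,
                             config$noise_1f_exponent,
                             sd = config$sensor_noise_sd)
    edat <- array(NA_real_, c(n_trials, length(keep), n_samp))
    for (tr in seq_len(n_trials)) {
      sig <- Mix %*% pdat[tr, , ]
      ncols <- (tr - 1L) * length(keep) + seq_along(keep)
      edat[tr, , ] <- sig + t(snoise[, ncols, drop = FALSE])
    }
    epochs <- epoch_set(edat, fs, t0, labels, chan_ids, pos,
                        subject_id = lat$subject)
  }

  kin <- simulate_kinematics(config, lat, labels)

  list(epochs = epochs, parcels = ptc, kinematics = kin$traces,
       trials = cbind(subject = lat$subject, kin$truth))
}

#' @keywords internal
#' @noRd
simulate_kinematics <- function(config, lat, labels) {
  fsb <- config$fs_behav
  n_trials <- length(labels)
  diff_extra <- (lat$behavior_diff_target -
                   (config$rt_ms$Slow[["mean"]] + config$mt_ms$Slow[["mean"]] -
                    config$rt_ms$Fast[["mean"]] - config$mt_ms$Fast[["mean"]]) / 1000)
  lux <- vector("list", n_trials)
  acc <- vector("list", n_trials)
  go_idx <- integer(n_trials)
  rt_all <- mt_all <- numeric(n_trials)
  pre <- 1.0
  for (tr in seq_len(n_trials)) {
    cond <- labels[tr]
    rt_mu <- config$rt_ms[[cond]][["mean"]] / 1000
    mt_mu <- config$mt_ms[[cond]][["mean"]] / 1000
    if (cond == "Slow") {  # subject-specific vigor difference, split RT/MT
      rt_mu <- rt_mu + diff_extra / 2
      mt_mu <- mt_mu + diff_extra / 2
    }
    rt <- max(0.12, stats::rnorm(1, rt_mu, config$rt_ms[[cond]][["sd"]] / 1000))
    mt <- max(0.12, stats::rnorm(1, mt_mu, config$mt_ms[[cond]][["sd"]] / 1000))
    rt <- round(rt * fsb) / fsb   # snap to the behavioral sample grid
    mt <- round(mt * fsb) / fsb
    dur <- pre + rt + 4 * mt + 0.5
    n <- round(dur * fsb) + 1L
    t <- (seq_len(n) - 1L) / fsb
    go_t <- pre
    peaks_t <- go_t + rt + (0:4) * mt
    l <- rep(0.1, n)
    # width proportional to MT keeps the lux profile scale-invariant, so
    # amplitude extraction carries no systematic condition difference
    w <- pmax(0.015, 0.15 * mt)
    # natural trial-to-trial variation in opening amplitude; without it,
    # sampling-grid artifacts of order 1e-3 masquerade as effects
    height <- max(0.5, stats::rnorm(1, 0.9, 0.05))
    for (pk in peaks_t) l <- l + height * exp(-(t - pk)^2 / (2 * w^2))
    amp <- 0.2 / mt
    a <- stats::rnorm(n, 0, 0.01)
    mv <- t >= go_t & t <= peaks_t[5]
    a[mv] <- stats::rnorm(sum(mv), 0, amp)
    lux[[tr]] <- l
    acc[[tr]] <- a
    go_idx[tr] <- round(go_t * fsb) + 1L
    rt_all[tr] <- rt
    mt_all[tr] <- mt
  }
  list(
    traces = kinematic_traces(lux, acc, fsb, go_idx, labels),
    truth = data.frame(trial = seq_len(n_trials), condition = labels,
                       rt = rt_all, mt = mt_all, stringsAsFactors = FALSE)
  )
}

#' Simulate only the behavioral arm of a cohort
#'
#' Generates the subject latents and kinematic traces without any
#' electrophysiological signals; useful for studying the planted
#' behavior-coherence association at larger subject counts.
#'
#' @param config a [sim_config()].
#' @return list with `kinematics` (per subject), `truth`, `config`.
#' @export
simulate_behavior_cohort <- function(config) {
  validate_sim_config(config)
  lat <- subject_latents(config)
  kin <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(fan_seed(config$rng_seed, s))
    n_cond <- config$n_trials_per_condition
    labels <- sample(rep(c("Fast", "Slow"), each = n_cond))
    simulate_kinematics(config, lat[s, ], labels)$traces
  })
  list(kinematics = kin, truth = list(subjects = lat), config = config)
}

#' Simulate a full synthetic cohort
#'
#' @param config a [sim_config()].
#' @param include_sensor generate sensor epochs as well as parcels.
#' @return a `cohort`: list with `subjects` (each as returned by
#'   [simulate_subject()]), `truth` (subject-level planted quantities plus
#'   per-trial RT/MT), and `config`.
#' @export
simulate_cohort <- function(config, include_sensor = TRUE) {
  validate_sim_config(config)
  lat <- subject_latents(config)
  subs <- lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, s, lat, include_sensor = include_sensor))
  trials <- do.call(rbind, lapply(subs, `[[`, "trials"))
  structure(list(
    subjects = subs,
    truth = list(subjects = lat, trials = trials),
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d trials/condition, band %s, contrast %.2f\n",
              x$config$n_subjects, x$config$n_trials_per_condition,
              x$config$band$name, x$config$kappa_slow - x$config$kappa_fast))
  invisible(x)
}
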