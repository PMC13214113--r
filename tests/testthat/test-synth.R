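# Synthetic cohort generator: config invariants, determinism, planted
# coupling and behavior, container round trips.

test_that("config invariants are enforced", {
  expect_error(sim_config(epoch_span = c(-1.2, 1.2)), "epoch_span too short")
  expect_error(sim_config(n_trials_per_condition = 3), "fold count")
  expect_error(sim_config(kappa_slow = 0.2, kappa_fast = 0.6),
               "kappa_fast <= kappa_slow")
  expect_error(sim_config(seed_parcel = "nonexistent"), "seed_parcel")
  expect_error(sim_config(coupled_parcels = "precentral-lh"),
               "cannot be coupled to itself")
})

test_that("identical seeds give identical cohorts; conditions are balanced", {
  a <- simulate_cohort(tiny_cfg(), include_sensor = TRUE)
  b <- simulate_cohort(tiny_cfg(), include_sensor = TRUE)
  expect_identical(a$subjects[[1]]$parcels$data, b$subjects[[1]]$parcels$data)
  expect_identical(a$subjects[[2]]$epochs$data, b$subjects[[2]]$epochs$data)
  expect_identical(a$subjects[[1]]$kinematics$lux, b$subjects[[1]]$kinematics$lux)
  expect_identical(a$truth$subjects, b$truth$subjects)
  d <- simulate_cohort(tiny_cfg(rng_seed = 8), include_sensor = FALSE)
  expect_false(identical(a$subjects[[1]]$parcels$data,
                         d$subjects[[1]]$parcels$data))
  expect_equal(unname(table(a$subjects[[1]]$parcels$labels)),
               c(8L, 8L), ignore_attr = TRUE)
})

test_that("planted coupling raises Slow iCoh for every subject and coupled parcel", {
  cfg <- sim_config(n_subjects = 3, n_trials_per_condition = 10,
                    kappa_sd = 0, rng_seed = 3)
  for (s in 1:3) {
    sub <- simulate_subject(cfg, s, include_sensor = FALSE)
    an <- band_filter_hilbert(sub$parcels)
    seed_i <- match(cfg$seed_parcel, an$parcel_names)
    x <- matrix(an$data[, seed_i, ], dim(an$data)[1])
    fast <- an$labels == "Fast"
    for (cp in cfg$coupled_parcels) {
      y <- matrix(an$data[, match(cp, an$parcel_names), ], dim(an$data)[1])
      ic <- compute_icoh(x, y, an$fs, an$t0)
      expect_gt(mean(ic[!fast, ]), mean(ic[fast, ]))
    }
  }
})

test_that("coherence contrast is monotone in the planted kappa contrast", {
  diffs <- vapply(c(0.2, 0.5, 0.8), function(ct) {
    cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 10,
                      kappa_slow = 0.5 + ct / 2, kappa_fast = 0.5 - ct / 2,
                      kappa_sd = 0, rng_seed = 11)
    sub <- simulate_subject(cfg, 1, include_sensor = FALSE)
    ic <- source_features(sub$parcels, cfg$band, "icoh")$icoh
    cp <- match(cfg$coupled_parcels, ic$unit_ids)
    fast <- ic$labels == "Fast"
    mean(ic$values[!fast, cp, ]) - mean(ic$values[fast, cp, ])
  }, 0)
  expect_true(all(diff(diffs) > 0))
  expect_true(all(diffs > 0))
})

test_that("equal coupling weights give a null cohort", {
  cfg <- sim_config(n_subjects = 3, n_trials_per_condition = 10,
                    kappa_slow = 0.5, kappa_fast = 0.5, rng_seed = 4)
  lat <- subject_latents(cfg)
  expect_true(all(lat$coherence_effect == 0))
  expect_true(all(lat$kappa_slow == lat$kappa_fast))
  sub <- simulate_subject(cfg, 1, lat, include_sensor = FALSE)
  ic <- source_features(sub$parcels, cfg$band, "icoh")$icoh
  fast <- ic$labels == "Fast"
  cp <- match(cfg$coupled_parcels, ic$unit_ids)
  expect_lt(abs(mean(ic$values[!fast, cp, ]) - mean(ic$values[fast, cp, ])),
            0.08)
})

test_that("generated behavior follows the configured condition ordering", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 15, rng_seed = 9)
  sub <- simulate_subject(cfg, 1, include_sensor = FALSE)
  bt <- behavior_table(sub$kinematics)
  expect_true(all(bt$valid))
  mt_f <- mean(bt$MT[bt$condition == "Fast"])
  mt_s <- mean(bt$MT[bt$condition == "Slow"])
  expect_lt(mt_f, mt_s)
  rt_f <- mean(bt$RT[bt$condition == "Fast"])
  expect_lt(rt_f, mean(bt$RT[bt$condition == "Slow"]))
  # extracted values match the generator's per-trial truth to one sample
  expect_lt(max(abs(bt$MT - sub$trials$mt)), 1.01 / cfg$fs_behav)
  expect_lt(max(abs(bt$RT - sub$trials$rt)), 1.01 / cfg$fs_behav)
})

test_that("behavior-only cohort realizes the planted vigor association", {
  cfg <- sim_config(n_subjects = 30, n_trials_per_condition = 20,
                    rng_seed = 21)
  bc <- simulate_behavior_cohort(cfg)
  expect_length(bc$kinematics, 30)
  behav <- do.call(rbind, lapply(seq_len(30), function(s)
    behavior_table(bc$kinematics[[s]], bc$truth$subjects$subject[s])))
  diffs <- summarize_behavior(behav)$diffs
  diffs <- diffs[match(bc$truth$subjects$subject, diffs$subject), ]
  r <- stats::cor(bc$truth$subjects$behavior_diff_target,
                  diffs$vigor_proxy_diff)
  expect_gt(r, 0.9)  # measured behavior tracks the planted targets
})

test_that("cohort round trip is lossless with informative failure modes", {
  coh <- simulate_cohort(tiny_cfg(), include_sensor = TRUE)
  dir <- tempfile("cohort")
  man <- write_cohort(coh, dir)
  rt <- read_cohort(dir)
  expect_identical(rt$subjects[[1]]$parcels$data, coh$subjects[[1]]$parcels$data)
  expect_identical(rt$subjects[[2]]$epochs$data, coh$subjects[[2]]$epochs$data)
  expect_identical(rt$subjects[[1]]$kinematics$lux,
                   coh$subjects[[1]]$kinematics$lux)
  expect_identical(rt$subjects[[1]]$parcels$labels,
                   coh$subjects[[1]]$parcels$labels)
  expect_equal(rt$truth$subjects$kappa_slow, coh$truth$subjects$kappa_slow)

  # tampered sidecar shape -> shape mismatch error
  sc_file <- file.path(dir, "sub-01_parcels_standard.json")
  sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  sc$shape[2] <- sc$shape[2] + 1L
  jsonlite::write_json(sc, sc_file, auto_unbox = TRUE, digits = NA)
  expect_error(read_cohort(dir), "shape mismatch")

  # missing sidecar -> distinct error
  file.remove(sc_file)
  expect_error(read_cohort(dir), "missing sidecar")

  # unknown container version -> distinct error
  dir2 <- tempfile("cohort2")
  write_cohort(coh, dir2)
  mf <- file.path(dir2, "manifest.json")
  man2 <- jsonlite::read_json(mf, simplifyVector = TRUE)
  man2$container_version <- "other-container-9"
  jsonlite::write_json(man2, mf, auto_unbox = TRUE, digits = NA)
  expect_error(read_cohort(dir2), "unknown container version")

  # manifest hash tracks the config
  dir3 <- tempfile("cohort3")
  man3 <- write_cohort(simulate_cohort(tiny_cfg(kappa_slow = 0.7),
                                       include_sensor = FALSE), dir3)
  expect_false(identical(man$config_hash, man3$config_hash))
})
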