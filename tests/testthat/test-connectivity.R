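# Imaginary coherence and symmetric orthogonalization.

test_that("iCoh identities: zero lag gives 0, quarter-cycle lag gives 1", {
  x <- nb_analytic(3, 385, seed = 1)
  g <- window_grid()
  expect_lt(max(compute_icoh(x, x, 128, -1.5, g)), 1e-6)
  expect_gt(min(compute_icoh(x, x * exp(1i * pi / 2), 128, -1.5, g)),
            1 - 1e-6)
  expect_lt(max(abs(compute_icoh(x, x * exp(-1i * pi / 2), 128, -1.5, g) - 1)),
            1e-6)
})

test_that("iCoh is symmetric, scale-invariant, and flags zero power", {
  x <- nb_analytic(4, 385, seed = 2)
  y <- nb_analytic(4, 385, seed = 3)
  a <- compute_icoh(x, y, 128, -1.5)
  expect_identical(a, compute_icoh(y, x, 128, -1.5))
  expect_equal(compute_icoh(3.7 * x, 0.02 * y, 128, -1.5), a,
               tolerance = 1e-12)
  y0 <- y; y0[2, ] <- 0
  flagged <- compute_icoh(x, y0, 128, -1.5)
  expect_true(all(is.na(flagged[2, ])))
  expect_true(all(!is.na(flagged[-2, ])))
})

test_that("window preconditions are enforced", {
  x <- nb_analytic(1, 385, seed = 4)
  g <- window_grid()
  expect_error(compute_icoh(x, x, 16, -1.5, g), "window sample count")
  expect_error(compute_icoh(Re(x), Re(x), 128, -1.5, g), "complex analytic")
})

test_that("orthogonal inputs are a fixed point of symmetric orthogonalization", {
  set.seed(5)
  m <- matrix(rnorm(256 * 3), 256, 3)
  m <- sweep(m, 2, colMeans(m))          # centred columns
  q <- qr.Q(qr(m)) %*% diag(c(2, 1, 0.5))  # centred and exactly orthogonal
  tc <- parcel_tc(array(t(q), c(1, 3, 256)), 128, 0, paste0("p", 1:3), "p1",
                  beta_band("standard"), "Fast")
  r <- symmetric_orthogonalize(tc)
  expect_true(r$report$converged)
  expect_lt(r$report$frobenius_change, 1e-10)
  expect_lt(r$report$max_abs_pairwise_zero_lag_correlation, 1e-8)
})

test_that("duplicated parcels raise a rank error naming the offenders", {
  set.seed(6)
  x <- rnorm(300)
  dat <- array(0, c(1, 3, 300))
  dat[1, 1, ] <- x; dat[1, 2, ] <- x; dat[1, 3, ] <- rnorm(300)
  tc <- parcel_tc(dat, 128, 0, c("pa", "pb", "pc"), "pa",
                  beta_band("standard"), "Fast")
  expect_error(symmetric_orthogonalize(tc), "rank-deficient.*pa, pb")
})

test_that("random instances orthogonalize cleanly and beat Gram-Schmidt", {
  # oracle: sequential (order-dependent) Gram-Schmidt as the comparison
  gs_change <- function(X) {
    Q <- X
    for (j in 2:ncol(X)) for (k in 1:(j - 1))
      Q[, j] <- Q[, j] - sum(Q[, j] * Q[, k]) / sum(Q[, k]^2) * Q[, k]
    sum((Q - X)^2)
  }
  set.seed(7)
  wins <- 0L
  for (i in 1:50) {
    X <- matrix(rnorm(512 * 4), 512, 4) %*%
      (diag(4) + matrix(runif(16, -0.3, 0.3), 4))
    tc <- parcel_tc(array(t(X), c(1, 4, 512)), 128, 0, paste0("p", 1:4),
                    "p1", beta_band("standard"), "Fast")
    r <- symmetric_orthogonalize(tc)
    expect_true(r$report$converged)
    expect_lt(r$report$max_abs_pairwise_zero_lag_correlation, 1e-8)
    Xc <- sweep(X, 2, colMeans(X))
    sym_change <- r$report$frobenius_change^2 * sum(Xc^2)
    if (sym_change <= gs_change(Xc)) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90% of draws
})

test_that("common zero-lag mixing barely moves iCoh after orthogonalization", {
  set.seed(8)
  fs <- 128; n <- 400
  mkband <- function() {
    x <- rnorm(n); xf <- stats::fft(x)
    f <- (seq_len(n) - 1) * fs / n
    xf[!(f >= 15 & f <= 25)] <- 0 + 0i
    Re(stats::fft(xf, inverse = TRUE)) / n
  }
  x <- mkband()
  y <- Re(betavigor:::analytic_signal_mat(matrix(mkband())) * 1i)[, 1] * 0.6 +
    0.4 * mkband()
  icoh_full <- function(a, b) {
    aa <- betavigor:::analytic_signal_mat(cbind(a, b))
    S <- mean(aa[, 1] * Conj(aa[, 2]))
    abs(Im(S / sqrt(mean(Mod(aa[, 1])^2) * mean(Mod(aa[, 2])^2))))
  }
  orth_icoh <- function(x1, y1) {
    dat <- array(0, c(1, 2, n)); dat[1, 1, ] <- x1; dat[1, 2, ] <- y1
    tc <- parcel_tc(dat, fs, 0, c("a", "b"), "a", beta_band("standard"),
                    "Fast")
    o <- symmetric_orthogonalize(tc)$parcels
    icoh_full(o$data[1, 1, ], o$data[1, 2, ])
  }
  i0 <- orth_icoh(x, y)
  m <- mkband()
  # estimator-level stability: the perturbation stays within the
  # finite-sample noise floor of the estimator (exact invariance holds
  # only in the infinite-sample limit)
  for (cm in c(0.1, 0.3))
    expect_lt(abs(orth_icoh(x + cm * m, y + cm * m) - i0), 0.06)
})

test_that("iCoh under independence matches the small-sample closed form", {
  # K iid complex samples of independent signals: Im of the sample
  # correlation is approximately N(0, 1/(2K)), so E|Im| ~ sqrt(1/(pi K))
  set.seed(9)
  K <- 64
  n_mc <- 4000
  x <- matrix(complex(real = rnorm(n_mc * 385), imaginary = rnorm(n_mc * 385)),
              n_mc, 385)
  y <- matrix(complex(real = rnorm(n_mc * 385), imaginary = rnorm(n_mc * 385)),
              n_mc, 385)
  ic <- compute_icoh(x, y, 128, -1.5)
  theo <- sqrt(1 / (pi * K))
  se <- stats::sd(ic) / sqrt(length(ic))
  expect_lt(abs(mean(ic) - theo), 2 * se + 0.1 * theo)
})

test_that("seed tensor honours the unit-count contract and planted margins", {
  # 68 parcels in, 67 units out
  set.seed(10)
  nm <- paste0("parc", 1:68)
  dat <- array(complex(real = rnorm(2 * 68 * 385),
                       imaginary = rnorm(2 * 68 * 385)), c(2, 68, 385))
  tc <- make_analytic_tc(dat, parcel_names = nm, seed_name = "parc33")
  tens <- seed_icoh_tensor(tc)
  expect_equal(dim(tens$values)[2], 67)
  expect_false("parc33" %in% tens$unit_ids)
  tc$seed_name <- "missing"
  expect_error(seed_icoh_tensor(tc), "seed parcel")

  # coupled parcels exceed uncoupled ones by a margin growing with kappa
  margins <- vapply(c(0.3, 0.8), function(kap) {
    n <- 385; n_tr <- 20
    seed_sig <- nb_analytic(n_tr, n, seed = 100)
    coupled <- kap * seed_sig * exp(1i * pi / 2) +
      (1 - kap) * nb_analytic(n_tr, n, seed = 101)
    uncoupled <- nb_analytic(n_tr, n, seed = 102)
    dat <- array(0i, c(n_tr, 3, n))
    dat[, 1, ] <- seed_sig; dat[, 2, ] <- coupled; dat[, 3, ] <- uncoupled
    tens <- seed_icoh_tensor(make_analytic_tc(dat,
                                              parcel_names = c("s", "c", "u"),
                                              seed_name = "s"))
    mean(tens$values[, 1, ]) - mean(tens$values[, 2, ])
  }, 0)
  expect_true(all(margins > 0))
  expect_gt(margins[2], margins[1])
})

test_that("independent parcels show no spurious seed coherence", {
  set.seed(11)
  n_tr <- 100
  dat <- array(complex(real = rnorm(n_tr * 8 * 385),
                       imaginary = rnorm(n_tr * 8 * 385)), c(n_tr, 8, 385))
  tens <- seed_icoh_tensor(make_analytic_tc(dat))
  per_trial <- apply(tens$values, c(1, 2), mean)
  grand <- mean(per_trial)
  alpha <- 0.01 / 7  # Bonferroni over the 7 non-seed parcels
  ps <- apply(per_trial, 2, function(v) stats::t.test(v, mu = grand)$p.value)
  expect_true(all(ps > alpha))
})
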