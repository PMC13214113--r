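# Group-level machinery: MAD trial screening, adjacency, paired cluster
# permutation tests, parcel ranking, sign-proportion permutation test.

mk_tensor <- function(v, labels = NULL) {
  d <- dim(v)
  if (is.null(labels)) labels <- rep(c("Fast", "Slow"), each = d[1] / 2)
  feature_tensor(v, paste0("u", seq_len(d[2])), "power",
                 beta_band("standard"), labels, "sensor")
}

test_that("screening masks flagged cells only, never altering retained values", {
  v <- array(1, c(20, 3, 2))
  v[4, 2, 1] <- 100  # one extreme value in one cell
  tens <- mk_tensor(v, labels = rep("Fast", 20))
  sc <- screen_trials(tens, by_condition = FALSE)
  expect_true(is.na(sc$tensor$values[4, 2, 1]))
  expect_equal(sum(is.na(sc$tensor$values)), 1)
  expect_equal(sc$removal_fraction, 1 / 120)
  # retained entries are bit-identical
  keep <- !is.na(sc$tensor$values)
  expect_identical(sc$tensor$values[keep], v[keep])
  # trial 4 still contributes to other cells' means
  m <- tensor_condition_means(sc$tensor)$Fast
  expect_equal(unname(m[1, 1]), mean(v[, 1, 1]))
})

test_that("screening is null on homogeneous data and deterministic per cell", {
  v <- array(3, c(12, 2, 2))
  sc <- screen_trials(mk_tensor(v))
  expect_equal(sc$removal_fraction, 0)

  set.seed(2)
  base <- c(rep(1, 11), 5)  # same pattern in every cell
  v2 <- array(rep(base, 4), c(12, 2, 2))
  sc2 <- screen_trials(mk_tensor(v2, labels = rep("Fast", 12)),
                       by_condition = FALSE)
  na_idx <- which(is.na(sc2$tensor$values), arr.ind = TRUE)
  expect_true(all(na_idx[, 1] == 12))
  expect_equal(nrow(na_idx), 4)

  # whole-trial variant masks the flagged trial everywhere
  sc3 <- screen_trials(mk_tensor(v2, labels = rep("Fast", 12)),
                       by_condition = FALSE, whole_trial = TRUE)
  expect_true(all(is.na(sc3$tensor$values[12, , ])))
})

test_that("adjacency follows the Euclidean radius rule", {
  # collinear points 0.015 apart: chain 1-2, 2-3, but not 1-3
  pos <- cbind(c(0, 0.015, 0.03), 0)
  g <- build_adjacency(pos, radius = 0.02)
  expect_equal(g$edges, rbind(c(1, 2), c(2, 3)), ignore_attr = TRUE)
  expect_equal(nrow(build_adjacency(cbind(c(0, 1, 2), 0), 0.02)$edges), 0)
  expect_equal(nrow(build_adjacency(pos, 0)$edges), 0)
  expect_warning(build_adjacency(rbind(pos, c(0, 0)), 0.02), "duplicate")
})

test_that("cluster test is antisymmetric and recovers a planted patch", {
  set.seed(3)
  n_sub <- 20; n_units <- 16
  pos <- cbind(rep(1:4, 4) * 0.015, rep(1:4, each = 4) * 0.015)
  adj <- build_adjacency(pos, 0.02)
  a <- matrix(rnorm(n_sub * n_units), n_sub)
  b <- matrix(rnorm(n_sub * n_units), n_sub)
  patch <- c(1, 2, 5, 6, 9)  # connected on the grid
  a[, patch] <- a[, patch] + 2
  r1 <- paired_cluster_permutation(a, b, adj, n_perm = 300, seed = 4)
  r2 <- paired_cluster_permutation(b, a, adj, n_perm = 300, seed = 4)
  expect_equal(r1$t_map, -r2$t_map, tolerance = 1e-12)
  expect_equal(lapply(r1$clusters, sort), lapply(r2$clusters, sort))
  sig_pos <- which(r1$p_values < 0.05 & r1$cluster_masses > 0)
  expect_gte(length(sig_pos), 1)
  found <- unlist(r1$clusters[sig_pos])
  expect_gte(length(intersect(found, patch)), 4)
})

test_that("cluster membership is invariant to unit relabelling", {
  set.seed(5)
  n_sub <- 12; n_units <- 9
  pos <- cbind(rep(1:3, 3) * 0.015, rep(1:3, each = 3) * 0.015)
  a <- matrix(rnorm(n_sub * n_units), n_sub); a[, c(1, 2, 4)] <- a[, c(1, 2, 4)] + 2
  b <- matrix(rnorm(n_sub * n_units), n_sub)
  perm <- sample(n_units)
  r <- paired_cluster_permutation(a, b, build_adjacency(pos, 0.02),
                                  n_perm = 200, seed = 6)
  rp <- paired_cluster_permutation(a[, perm], b[, perm],
                                   build_adjacency(pos[perm, ], 0.02),
                                   n_perm = 200, seed = 6)
  orig <- lapply(r$clusters, sort)
  back <- lapply(rp$clusters, function(cl) sort(perm[cl]))
  expect_setequal(vapply(orig, paste, "", collapse = ","),
                  vapply(back, paste, "", collapse = ","))
})

test_that("null cluster runs rarely produce significant clusters", {
  set.seed(7)
  n_runs <- 30
  pos <- cbind(rep(1:4, 4) * 0.015, rep(1:4, each = 4) * 0.015)
  adj <- build_adjacency(pos, 0.02)
  fp <- 0L
  for (i in seq_len(n_runs)) {
    a <- matrix(rnorm(10 * 16), 10)
    b <- matrix(rnorm(10 * 16), 10)
    r <- paired_cluster_permutation(a, b, adj, n_perm = 200, seed = 100 + i)
    if (length(r$p_values) > 0 && min(r$p_values) < 0.05) fp <- fp + 1L
  }
  # alpha + 2 binomial se at n_runs = 30
  expect_lte(fp / n_runs, 0.05 + 2 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("parcel ranking sorts by |mean t| with lexicographic ties", {
  tm <- rbind(pb = c(3, 3), pa = c(-4, -4), pc = c(1, 1), pd = c(-3, -3))
  r <- rank_parcels_by_t(tm, k = 3)
  expect_equal(r$unit, c("pa", "pb", "pd"))  # tie 3 vs -3: name order
  expect_equal(r$mean_t, c(-4, 3, -3))
  expect_equal(nrow(rank_parcels_by_t(tm, k = 10)), 4)
})

test_that("sign-proportion test responds to planted direction and calibrates", {
  set.seed(8)
  # parcel means strongly negative with subject-level noise: the flip
  # null then explores intermediate proportions, giving the test power
  # (a noise-free homogeneous shift would saturate both the observed
  # statistic and its null at 1)
  d_neg <- matrix(rnorm(15 * 21, mean = -1, sd = 1.2), 15, 21)
  r <- sign_proportion_permutation(d_neg, n_perm = 500, seed = 9)
  expect_gte(r$prop_negative, 0.9)
  expect_lt(r$p, 0.05)
  expect_gt(r$z, 0)

  # symmetric null: rejection rate controlled over 20 replicates
  rej <- 0L; zs <- numeric(20)
  for (i in 1:20) {
    d0 <- matrix(rnorm(10 * 21), 10, 21)
    r0 <- sign_proportion_permutation(d0, n_perm = 300, seed = 10 + i)
    zs[i] <- r0$z
    if (r0$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 4)
  expect_lt(abs(mean(zs)), 0.75)

  expect_warning(sign_proportion_permutation(matrix(rnorm(21), 1), 300, 1),
                 "single subject")
  expect_warning(sign_proportion_permutation(d_neg, n_perm = 100, seed = 1),
                 "n_perm < 200")
})
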