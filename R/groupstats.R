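# Group-level machinery: MAD trial screening of feature tensors, spatial
# adjacency, paired cluster-based permutation tests, parcel ranking, and
# the sign-proportion permutation test.

#' Screen trials of a feature tensor by the 3xMAD rule
#'
#' Within each condition, flags per (unit, window) cell the trials with
#' `|x - median| > n_mad * MAD` and masks them (NA) so they are excluded
#' from that cell's across-trial mean only; retained values are never
#' altered. Cells where more than half the trials would be removed are
#' retained unmasked with a warning.
#'
#' @param tensor a [feature_tensor()] (one subject).
#' @param n_mad multiplier.
#' @param by_condition screen within condition (default) or pooled.
#' @param whole_trial if `TRUE`, a trial flagged in any cell is masked in
#'   all cells (whole-trial removal) instead of cell-wise.
#' @return list: `tensor` (masked copy), `removal_fraction`.
#' @export
screen_trials <- function(tensor, n_mad = 3, by_condition = TRUE,
                          whole_trial = FALSE) {
  stopifnot(inherits(tensor, "feature_tensor"))
  v <- tensor$values
  d <- dim(v)
  groups <- if (by_condition) split(seq_len(d[1]), tensor$labels)
            else list(all = seq_len(d[1]))
  mask <- array(FALSE, d)
  warned <- 0L
  for (idx in groups) {
    if (length(idx) < 10L)
      warning("screen_trials: fewer than 10 trials in a condition")
    for (u in seq_len(d[2])) for (w in seq_len(d[3])) {
      x <- v[idx, u, w]
      med <- stats::median(x, na.rm = TRUE)
      m <- mad_raw(x)
      fl <- abs(x - med) > n_mad * m
      fl[is.na(fl)] <- FALSE
      if (mean(fl) > 0.5) {
        warned <- warned + 1L
        next  # cell retained with note
      }
      mask[idx, u, w] <- fl
    }
  }
  if (warned > 0L)
    warning("screen_trials: ", warned,
            " cell(s) would lose >50% of trials; retained unmasked")
  if (whole_trial) {
    bad <- which(apply(mask, 1, any))
    mask[bad, , ] <- TRUE
  }
  out <- tensor
  out$values[mask] <- NA_real_
  list(tensor = out, removal_fraction = mean(mask))
}

#' Across-trial means of a (screened) tensor per condition
#'
#' @param tensor a [feature_tensor()] (possibly masked).
#' @return list of units x windows matrices, one per condition.
#' @export
tensor_condition_means <- function(tensor) {
  lapply(split(seq_along(tensor$labels), tensor$labels), function(idx) {
    m <- apply(tensor$values[idx, , , drop = FALSE], c(2, 3), mean,
               na.rm = TRUE)
    dimnames(m) <- dimnames(tensor$values)[2:3]
    m
  })
}

#' Spatial adjacency graph from 2-D positions
#'
#' Units closer than `radius` (Euclidean) are connected. Duplicate
#' positions are allowed with a warning (distance-zero edges).
#'
#' @param positions units x 2 matrix.
#' @param radius connection radius (0.02 montage units by default).
#' @return list: `n_units`, `edges` (m x 2 integer matrix), `graph`
#'   (igraph object).
#' @export
build_adjacency <- function(positions, radius = 0.02) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  dd <- as.matrix(stats::dist(positions))
  if (n > 1 && any(dd[upper.tri(dd)] == 0))
    warning("build_adjacency: duplicate positions (distance-zero edges)")
  adj <- dd < radius
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  colnames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  list(n_units = n, edges = edges, graph = g)
}

cluster_masses <- function(tvals, threshold, graph_obj) {
  # connected supra-threshold clusters, split by sign; returns list of
  # (members, mass)
  res <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvals > threshold)
    if (length(supra) == 0) next
    sg <- igraph::induced_subgraph(graph_obj, supra)
    comp <- igraph::components(sg)$membership
    for (k in unique(comp)) {
      members <- supra[comp == k]
      res[[length(res) + 1L]] <- list(units = members,
                                      mass = sum(tvals[members]),
                                      sign = sgn)
    }
  }
  res
}

#' Paired cluster-based spatial permutation test
#'
#' Per-unit paired t statistics; units exceeding the two-sided critical t
#' at `alpha` (df = n-1) are clustered by graph connectivity and sign;
#' cluster mass is the summed t. The null distribution is the maximum
#' absolute cluster mass over random within-subject condition swaps (sign
#' flips of the paired differences), with the +1 permutation correction.
#'
#' @param cond_a,cond_b subjects x units matrices of paired means.
#' @param adjacency from [build_adjacency()].
#' @param alpha cluster-forming threshold level (two-sided).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: `t_map`, `threshold_t`, `clusters` (unit index lists),
#'   `cluster_masses`, `p_values`, `n_permutations`.
#' @export
paired_cluster_permutation <- function(cond_a, cond_b, adjacency,
                                       alpha = 0.05, n_perm = 1000,
                                       seed = 1L) {
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  n <- nrow(cond_a)
  if (n < 5L) stop("paired_cluster_permutation: need >= 5 subjects")
  d <- cond_a - cond_b
  tvec <- function(x) {
    m <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    m / (s / sqrt(nrow(x)))
  }
  tobs <- tvec(d)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  obs <- cluster_masses(tobs, tcrit, adjacency$graph)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tp <- tvec(d * flips)
    cl <- cluster_masses(tp, tcrit, adjacency$graph)
    null_max[i] <- if (length(cl) == 0) 0
                   else max(vapply(cl, function(z) abs(z$mass), 0))
  }
  p <- vapply(obs, function(z)
    (1 + sum(null_max >= abs(z$mass))) / (1 + n_perm), 0)
  list(
    t_map = tobs,
    threshold_t = tcrit,
    clusters = lapply(obs, `[[`, "units"),
    cluster_masses = vapply(obs, `[[`, 0, "mass"),
    p_values = p,
    n_permutations = n_perm
  )
}

#' Rank spatial units by absolute mean t across windows
#'
#' @param t_matrix units x windows matrix of t values with unit rownames.
#' @param k how many to return (the full list if `k` exceeds the count).
#' @return data.frame `unit`, `mean_t`, ordered by decreasing `|mean_t|`;
#'   ties broken lexicographically by unit name.
#' @export
rank_parcels_by_t <- function(t_matrix, k = 5) {
  mt <- rowMeans(t_matrix)
  nm <- rownames(t_matrix)
  if (is.null(nm)) nm <- as.character(seq_along(mt))
  ord <- order(-abs(mt), nm)
  k <- min(k, length(mt))
  data.frame(unit = nm[ord][seq_len(k)], mean_t = unname(mt[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Sign-proportion permutation test over a parcel subset
#'
#' Observed statistic: proportion of parcels whose across-subject mean
#' Fast-Slow difference is negative. Null: each subject's whole difference
#' map has its sign flipped at random; one-sided p for an excess of
#' negative parcels, with the +1 correction; z is the observed proportion
#' standardized against the null distribution.
#'
#' @param diffs subjects x parcels matrix of Fast-Slow differences.
#' @param n_perm permutations (warns below 200).
#' @param seed RNG seed.
#' @return list: `prop_negative`, `z`, `p`, `n_permutations`.
#' @export
sign_proportion_permutation <- function(diffs, n_perm = 1000, seed = 1L) {
  diffs <- rbind(diffs)
  n <- nrow(diffs)
  if (n_perm < 200) warning("sign_proportion_permutation: n_perm < 200")
  if (n < 2L)
    warning("sign_proportion_permutation: degenerate null with a single subject")
  obs <- mean(colMeans(diffs) < 0)
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    null[i] <- mean(colMeans(diffs * flips) < 0)
  }
  z <- (obs - mean(null)) / stats::sd(null)
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(prop_negative = obs, z = z, p = p, n_permutations = n_perm)
}
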