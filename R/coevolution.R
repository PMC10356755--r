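#' Eligible host-phage trajectory pairs
#'
#' Forms the Cartesian product of host and phage mutation trajectories within
#' a community and removes pairs in which either trajectory has fewer than
#' `min_nonzero` nonzero frequencies, minimising the influence of zeros on
#' the correlations. The removal count is recorded.
#'
#' @param host,phage trajectory matrices (see [build_trajectory_matrix()])
#'   sharing the same timepoint grid.
#' @param min_nonzero minimum nonzero observations required in both
#'   trajectories (default 3).
#' @return list: `pairs` tibble (`host_mutation_id, phage_mutation_id`),
#'   `n_pairs_removed`, `host_ids`, `phage_ids`.
#' @export
eligible_pairs <- function(host, phage, min_nonzero = 3) {
  if (!identical(colnames(host), colnames(phage))) {
    stop("host and phage matrices use different timepoint grids")
  }
  h_ok <- rownames(host)[rowSums(host > 0) >= min_nonzero]
  p_ok <- rownames(phage)[rowSums(phage > 0) >= min_nonzero]
  pairs <- tidyr::expand_grid(host_mutation_id = h_ok,
                              phage_mutation_id = p_ok)
  list(pairs = pairs,
       n_pairs_removed = nrow(host) * nrow(phage) - nrow(pairs),
       host_ids = h_ok, phage_ids = p_ok)
}

#' Pearson correlations for host-phage trajectory pairs
#'
#' Sample Pearson r over the full timepoint grid (zeros are real
#' "not detected" frequencies and are included). Pairs involving a
#' zero-variance trajectory, for which r is undefined, are excluded and
#' counted.
#'
#' @param pairs pair list from [eligible_pairs()] or a tibble of pairs.
#' @param host,phage trajectory matrices.
#' @param community_id label stored in the result.
#' @return a `correlation_set`: `community_id`, `pairs` tibble with `r`,
#'   `null_r` (NULL until [permuted_time_null()] is run), `n_pairs_removed`,
#'   `n_zero_variance`.
#' @export
pair_correlations <- function(pairs, host, phage, community_id = "community") {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    n_removed <- pairs$n_pairs_removed
    pairs <- pairs$pairs
  } else {
    n_removed <- 0L
  }
  h_sd <- apply(host, 1, stats::sd)
  p_sd <- apply(phage, 1, stats::sd)
  ok <- h_sd[pairs$host_mutation_id] > 0 & p_sd[pairs$phage_mutation_id] > 0
  n_zero_var <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  r <- if (nrow(pairs) > 0) {
    cm <- stats::cor(t(host[unique(pairs$host_mutation_id), , drop = FALSE]),
                     t(phage[unique(pairs$phage_mutation_id), , drop = FALSE]))
    cm[cbind(pairs$host_mutation_id, pairs$phage_mutation_id)]
  } else {
    numeric(0)
  }
  structure(list(community_id = community_id,
                 pairs = tibble::tibble(pairs, r = r),
                 null_r = NULL,
                 n_pairs_removed = n_removed,
                 n_zero_variance = n_zero_var),
            class = "correlation_set")
}

#' Permuted-time null correlations
#'
#' For each permutation round, every trajectory's timepoint labels are
#' shuffled independently (destroying temporal coupling between host and
#' phage while preserving each trajectory's marginal frequencies) and the
#' correlations of the same eligible pairs are recomputed.
#'
#' @param host,phage trajectory matrices.
#' @param pairs pair tibble or the list from [eligible_pairs()].
#' @param n_perm permutation rounds (default 100).
#' @param seed integer RNG seed.
#' @return matrix of null correlations, pairs x rounds (pool with `c()` for
#'   the community-level null distribution); zero-variance pairs excluded as in
#'   [pair_correlations()].
#' @export
permuted_time_null <- function(host, phage, pairs, n_perm = 100, seed = 1) {
  stopifnot(n_perm >= 1)
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  h_sd <- apply(host, 1, stats::sd)
  p_sd <- apply(phage, 1, stats::sd)
  ok <- h_sd[pairs$host_mutation_id] > 0 & p_sd[pairs$phage_mutation_id] > 0
  pairs <- pairs[ok, , drop = FALSE]
  tcol <- ncol(host)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(NA_real_, nrow(pairs), n_perm)
  hu <- unique(pairs$host_mutation_id)
  pu <- unique(pairs$phage_mutation_id)
  for (b in seq_len(n_perm)) {
    hp <- host[hu, , drop = FALSE]
    pp <- phage[pu, , drop = FALSE]
    for (i in seq_len(nrow(hp))) hp[i, ] <- hp[i, sample.int(tcol)]
    for (i in seq_len(nrow(pp))) pp[i, ] <- pp[i, sample.int(tcol)]
    cm <- stats::cor(t(hp), t(pp))
    out[, b] <- cm[cbind(pairs$host_mutation_id, pairs$phage_mutation_id)]
  }
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  out
}

sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(NA_real_)
  z <- x - mean(x)
  (sum(z^3) / n) / (sum(z^2) / n)^1.5
}

#' Compare observed correlations with their permuted-time null
#'
#' Two-sample KS statistic between the observed pair correlations and the
#' pooled permuted-time null. The permutation p-value is built from
#' `test_draws`: extra rounds of the same per-trajectory time permutation
#' (columns of a second [permuted_time_null()] matrix). Each round yields a
#' complete pseudo-observed correlation vector whose KS distance to the null
#' pool is computed; this preserves the dependence between pairs that share
#' a trajectory, which is what makes the test exact under temporal
#' exchangeability. Without `test_draws`, labels are permuted freely between
#' the pooled observed and null values - a rougher fallback that ignores
#' that dependence.
#'
#' Also reports the skewness of the observed r and a direction diagnostic,
#' the signed area between the null and observed ECDFs
#' (= mean(obs) - mean(null)): negative when the observed correlations are
#' stochastically smaller (skewed negative) relative to the null.
#'
#' @param obs_r numeric vector of observed pair correlations.
#' @param null_r null correlations: matrix pairs x rounds (pooled for the
#'   reference distribution), or a numeric vector.
#' @param n_perm permutations for the fallback p-value (ignored when
#'   `test_draws` is given, where the column count is used).
#' @param seed integer RNG seed (used by the fallback; recorded either way).
#' @param test_draws optional pairs x rounds matrix of pseudo-observed
#'   correlation vectors from independent permutation rounds.
#' @return a `perm_test_result` with extras `direction` and `skewness`.
#' @export
compare_to_null <- function(obs_r, null_r = NULL, n_perm = 999, seed = 1,
                            test_draws = NULL) {
  if (length(obs_r) == 0 || length(null_r) == 0) {
    stop("compare_to_null requires non-empty observed and null vectors")
  }
  pool <- as.numeric(null_r)
  extra <- list(direction = mean(obs_r) - mean(pool),
                skewness = sample_skewness(obs_r))
  observed <- ks_statistic(obs_r, pool)
  if (!is.null(test_draws)) {
    test_draws <- as.matrix(test_draws)
    stopifnot(nrow(test_draws) == length(obs_r))
    null_values <- apply(test_draws, 2, ks_statistic, pool)
    n_perm <- ncol(test_draws)
    p <- (1 + sum(null_values >= observed)) / (n_perm + 1)
    res <- new_perm_test_result("KS D (observed vs permuted-time null)",
                                observed, p, n_perm, seed, null_values,
                                extra)
  } else {
    res <- permutation_pvalue(obs_r, pool, ks_statistic, n_perm = n_perm,
                              seed = seed, unit = "value",
                              statistic_name =
                                "KS D (observed vs permuted-time null)")
    res[names(extra)] <- extra
  }
  res
}

#' Compare pooled correlation distributions between treatments
#'
#' Pools pair correlations across the replicate communities of each
#' treatment and tests the two pooled distributions with a permutational
#' two-sample KS test. By default individual r values are permuted between
#' treatments; `unit = "block"` permutes whole-community labels instead.
#'
#' @param corr_sets_a,corr_sets_b lists of `correlation_set`s (one per
#'   community) for the two treatments.
#' @param n_perm permutations (default 10000).
#' @param seed integer RNG seed.
#' @param unit `"value"` or `"block"` (communities as blocks).
#' @return a `perm_test_result`.
#' @export
compare_treatments <- function(corr_sets_a, corr_sets_b, n_perm = 10000,
                               seed = 1, unit = c("value", "block")) {
  unit <- match.arg(unit)
  ra <- lapply(corr_sets_a, function(s) s$pairs$r)
  rb <- lapply(corr_sets_b, function(s) s$pairs$r)
  if (unit == "value") {
    permutation_pvalue(unlist(ra), unlist(rb), ks_statistic, n_perm = n_perm,
                       seed = seed, unit = "value",
                       statistic_name = "KS D (treatment comparison)")
  } else {
    permutation_pvalue(ra, rb, ks_statistic, n_perm = n_perm, seed = seed,
                       unit = "block",
                       statistic_name = "KS D (treatment comparison)")
  }
}

#' Mutations that reached high frequency
#'
#' Mutations whose maximum frequency over the timepoint grid strictly
#' exceeds `threshold` (default 0.3), sorted by decreasing maximum.
#'
#' @param x mutation record tibble, or a trajectory matrix (gene ids then
#'   come from `gene_map`).
#' @param threshold strict lower bound on the maximum frequency.
#' @param gene_map optional named character vector mutation_id -> gene_id
#'   used when `x` is a matrix.
#' @return tibble `mutation_id, gene_id, max_freq`.
#' @export
high_frequency_report <- function(x, threshold = 0.3, gene_map = NULL) {
  if (is.matrix(x)) {
    mx <- if (nrow(x)) apply(x, 1, max) else numeric(0)
    ids <- rownames(x)
    genes <- if (!is.null(gene_map)) unname(gene_map[ids])
             else rep(NA_character_, length(ids))
  } else {
    cols <- tp_cols(record_timepoints(x))
    mx <- if (nrow(x)) apply(as.matrix(x[, cols, drop = FALSE]), 1, max)
          else numeric(0)
    ids <- x$mutation_id
    genes <- x$gene_id
  }
  keep <- mx > threshold
  out <- tibble::tibble(mutation_id = ids[keep], gene_id = genes[keep],
                        max_freq = mx[keep])
  out[order(-out$max_freq, out$mutation_id), , drop = FALSE]
}
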