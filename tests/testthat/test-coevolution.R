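traj_matrix <- function(m, prefix = "mut") {
  rownames(m) <- sprintf("%s%02d", prefix, seq_len(nrow(m)))
  colnames(m) <- paste0("t", c(1, 4, 7, 10, 14))
  m
}

test_that("pair eligibility enforces the three-nonzero rule on both sides", {
  host <- traj_matrix(rbind(c(0.1, 0.2, 0.3, 0, 0),
                            c(0.1, 0.2, 0, 0, 0)), "h")
  phage <- traj_matrix(rbind(c(0, 0.1, 0.2, 0.3, 0)), "p")
  ep <- eligible_pairs(host, phage, 3)
  expect_equal(nrow(ep$pairs), 1)
  expect_equal(ep$pairs$host_mutation_id, "h01")
  expect_equal(ep$n_pairs_removed, 1)

  full_h <- traj_matrix(matrix(0.2, 10, 5), "h")
  full_p <- traj_matrix(matrix(0.3, 8, 5), "p")
  expect_equal(nrow(eligible_pairs(full_h, full_p, 3)$pairs), 80)

  # monotone: raising the threshold never adds pairs
  n_at <- vapply(1:5, function(k)
    nrow(eligible_pairs(host, phage, k)$pairs), numeric(1))
  expect_true(all(diff(n_at) <= 0))

  bad <- phage
  colnames(bad) <- paste0("t", 1:5)
  expect_error(eligible_pairs(host, bad), "grids")
})

test_that("pair correlations are exact on closed-form cases", {
  f <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h <- traj_matrix(rbind(f, f), "h")
  p <- traj_matrix(rbind(1 - f, f, c(0.6, 0.5, 0.3, 0.1, 0)), "p")
  cs <- pair_correlations(eligible_pairs(h, p, 1), h, p, "c1")
  r <- cs$pairs$r
  anti <- r[cs$pairs$phage_mutation_id == "p01"]
  same <- r[cs$pairs$phage_mutation_id == "p02"]
  expect_equal(anti, c(-1, -1))
  expect_equal(same, c(1, 1))

  h2 <- traj_matrix(rbind(c(0, 0.1, 0.3, 0.5, 0.6)), "h")
  p2 <- traj_matrix(rbind(c(0.6, 0.5, 0.3, 0.1, 0)), "p")
  expect_equal(pair_correlations(eligible_pairs(h2, p2, 1), h2, p2)$pairs$r,
               -1)
  p3 <- traj_matrix(rbind(rev(c(0.6, 0.5, 0.3, 0.1, 0))), "p")
  expect_equal(pair_correlations(eligible_pairs(h2, p3, 1), h2, p3)$pairs$r,
               1, tolerance = 1e-12)
})

test_that("zero-variance trajectories are excluded and counted", {
  h <- traj_matrix(rbind(c(0.1, 0.2, 0.3, 0.4, 0.5),
                         c(0.2, 0.2, 0.2, 0.2, 0.2)), "h")
  p <- traj_matrix(rbind(c(0.5, 0.4, 0.3, 0.2, 0.1)), "p")
  cs <- pair_correlations(eligible_pairs(h, p, 3), h, p)
  expect_equal(nrow(cs$pairs), 1)
  expect_equal(cs$n_zero_variance, 1)
})

test_that("pair correlations are invariant to reordering matrix rows", {
  set.seed(11)
  h <- traj_matrix(matrix(runif(25), 5), "h")
  p <- traj_matrix(matrix(runif(20), 4), "p")
  cs1 <- pair_correlations(eligible_pairs(h, p, 1), h, p)
  perm_h <- h[sample(nrow(h)), ]
  perm_p <- p[sample(nrow(p)), ]
  cs2 <- pair_correlations(eligible_pairs(perm_h, perm_p, 1), perm_h, perm_p)
  key1 <- paste(cs1$pairs$host_mutation_id, cs1$pairs$phage_mutation_id)
  key2 <- paste(cs2$pairs$host_mutation_id, cs2$pairs$phage_mutation_id)
  expect_equal(cs1$pairs$r[order(key1)], cs2$pairs$r[order(key2)])
})

test_that("the permuted-time null is reproducible and centred on zero", {
  set.seed(12)
  h <- traj_matrix(matrix(runif(40), 8), "h")
  p <- traj_matrix(matrix(runif(30), 6), "p")
  ep <- eligible_pairs(h, p, 1)
  n1 <- permuted_time_null(h, p, ep, n_perm = 25, seed = 5)
  n2 <- permuted_time_null(h, p, ep, n_perm = 25, seed = 5)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(48, 25))

  big <- permuted_time_null(h, p, ep, n_perm = 100, seed = 6)
  se <- sd(big) / sqrt(length(big))
  expect_lt(abs(mean(big)), 3 * se + 0.02)
})

test_that("a two-timepoint grid degenerates to correlations of +/-1", {
  h <- matrix(c(0.1, 0.6), 1, dimnames = list("h1", c("t1", "t4")))
  p <- matrix(c(0.5, 0.2), 1, dimnames = list("p1", c("t1", "t4")))
  nl <- permuted_time_null(h, p, eligible_pairs(h, p, 1), n_perm = 50,
                           seed = 2)
  expect_true(all(abs(abs(nl) - 1) < 1e-12))
})

test_that("comparison to the null reports direction and calibrated p-values", {
  set.seed(13)
  null_m <- matrix(rnorm(50 * 30, 0, 0.4), 50, 30)
  draws <- matrix(rnorm(50 * 499, 0, 0.4), 50, 499)
  obs_shift <- rowMeans(null_m) - 0.5
  res <- compare_to_null(obs_shift, null_m, test_draws = draws)
  expect_equal(res$p_value, 1 / 500)
  expect_lt(res$direction, 0)

  # observed drawn from the same distribution: moderate p, sign arbitrary
  obs_null <- rnorm(50, 0, 0.4)
  res0 <- compare_to_null(obs_null, null_m,
                          test_draws = draws[, 1:199, drop = FALSE])
  expect_gt(res0$p_value, 0.05)

  # p-value deterministic given draws; fallback deterministic given seed
  r1 <- compare_to_null(obs_null, null_m,
                        test_draws = draws[, 1:99, drop = FALSE])
  r2 <- compare_to_null(obs_null, null_m,
                        test_draws = draws[, 1:99, drop = FALSE])
  expect_identical(r1$p_value, r2$p_value)
  f1 <- compare_to_null(obs_shift, as.numeric(null_m), n_perm = 99, seed = 1)
  f2 <- compare_to_null(obs_shift, as.numeric(null_m), n_perm = 99, seed = 1)
  expect_identical(f1$p_value, f2$p_value)
  expect_lt(f1$p_value, 0.05)
})

test_that("type-I error of the null comparison is near nominal", {
  set.seed(14)
  pv <- vapply(1:120, function(i) {
    null_m <- matrix(rnorm(20 * 15), 20, 15)
    draws <- matrix(rnorm(20 * 99), 20, 99)
    obs <- rnorm(20)
    compare_to_null(obs, null_m, test_draws = draws)$p_value
  }, numeric(1))
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("treatment comparison pools communities and finds shifts", {
  set.seed(15)
  mk_set <- function(r, id) {
    structure(list(community_id = id,
                   pairs = tibble::tibble(host_mutation_id = "h",
                                          phage_mutation_id = "p", r = r),
                   null_r = NULL, n_pairs_removed = 0L,
                   n_zero_variance = 0L), class = "correlation_set")
  }
  base <- lapply(1:3, function(i) mk_set(runif(40, -1, 1), paste0("a", i)))
  same <- lapply(1:3, function(i) mk_set(base[[i]]$pairs$r, paste0("b", i)))
  eq <- compare_treatments(base, same, n_perm = 99, seed = 1)
  expect_equal(eq$observed, 0)
  expect_equal(eq$p_value, 1)

  shifted <- lapply(1:3, function(i)
    mk_set(pmin(1, base[[i]]$pairs$r + 0.8), paste0("c", i)))
  sh <- compare_treatments(base, shifted, n_perm = 999, seed = 2)
  expect_gt(sh$observed, 0.3)
  expect_equal(sh$p_value, 1 / 1000)

  blk <- compare_treatments(base, shifted, n_perm = 200, seed = 3,
                            unit = "block")
  expect_gt(blk$observed, 0.3)
})

test_that("high-frequency report applies a strict threshold", {
  rec <- make_records(rbind(c(0.31, 0, 0, 0, 0),
                            c(0.30, 0, 0, 0, 0),
                            c(0, 0.5, 0.9, 0, 0)),
                      gene_id = "g")
  rec$gene_id <- c("g1", "g2", "g3")
  rep <- high_frequency_report(rec, 0.3)
  expect_equal(rep$gene_id, c("g3", "g1"))
  expect_equal(rep$max_freq, c(0.9, 0.31))
  expect_equal(nrow(high_frequency_report(rec[0, ], 0.3)), 0)
  # counting oracle against a brute-force loop
  cols <- paste0("t", c(1, 4, 7, 10, 14))
  brute <- sum(apply(rec[, cols], 1, max) > 0.3)
  expect_equal(nrow(rep), brute)
})
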