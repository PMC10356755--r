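test_that("KS statistic matches enumeration of ECDF steps", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_statistic(c(0.1, 0.4), c(0.2, 0.3)), 0.5)
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
  set.seed(1)
  a <- rnorm(40)
  b <- rnorm(25, 0.5)
  # symmetry and agreement with the reference implementation
  expect_equal(ks_statistic(a, b), ks_statistic(b, a))
  expect_equal(ks_statistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  # invariance under a strictly monotone transform of both samples
  expect_equal(ks_statistic(exp(a), exp(b)), ks_statistic(a, b))
})

test_that("permutation p-values use the add-one estimator and a seed", {
  const <- function(a, b) 1
  res <- permutation_pvalue(rnorm(5), rnorm(5), const, n_perm = 99, seed = 3)
  expect_equal(res$p_value, 1)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))

  a <- c(0.1, 0.2, 0.3)
  b <- c(5.1, 5.2, 5.3)
  r1 <- permutation_pvalue(a, b, ks_statistic, n_perm = 199, seed = 9)
  r2 <- permutation_pvalue(a, b, ks_statistic, n_perm = 199, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_values, r2$null_values)
  expect_length(r1$null_values, 199)

  expect_error(permutation_pvalue(1, numeric(0), ks_statistic, 10, 1),
               "relabelings")
})

test_that("block permutation agrees with exhaustive 3-vs-3 enumeration", {
  set.seed(42)
  blocks <- replicate(6, runif(8), simplify = FALSE)
  ga <- blocks[1:3]
  gb <- blocks[4:6]
  obs <- ks_statistic(unlist(ga), unlist(gb))
  combos <- utils::combn(6, 3)
  stats <- apply(combos, 2, function(idx) {
    ks_statistic(unlist(blocks[idx]), unlist(blocks[-idx]))
  })
  p_exact <- mean(stats >= obs)
  res <- permutation_pvalue(ga, gb, ks_statistic, n_perm = 4000, seed = 7,
                            unit = "block")
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 4000)
})

test_that("Bray-Curtis distances match hand computation and vegan", {
  m <- rbind(a = c(1, 2, 0), b = c(0, 2, 2), c = c(1, 2, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 3 / 7)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  disjoint <- rbind(c(1, 0), c(0, 2))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 1), c(1, 1))), "nonnegative")

  set.seed(8)
  big <- matrix(runif(60), 6, 10)
  expect_equal(max(abs(bray_curtis(big) -
                         as.matrix(vegan::vegdist(big, "bray")))), 0,
               tolerance = 1e-12)
})

test_that("PCoA recovers configurations from their distances", {
  # two points at distance d sit at +/- d/2 on one axis
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  ord2 <- pcoa(d2)
  expect_equal(ncol(ord2$coordinates), 1)
  expect_equal(sort(ord2$coordinates[, 1]), c(-0.4, 0.4))

  # known planar configuration: recovered coordinates reproduce it up to
  # rotation/reflection
  set.seed(3)
  pts <- matrix(rnorm(14), 7, 2)
  ord <- pcoa(as.matrix(dist(pts)))
  expect_equal(ncol(ord$coordinates), 2)
  proc <- vegan::procrustes(pts, ord$coordinates, symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-8)
  # and agrees with the reference classical scaling
  ref <- stats::cmdscale(as.matrix(dist(pts)), k = 2, eig = TRUE)
  expect_equal(abs(ord$coordinates), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_equal(sum(ord$proportion_explained), 1, tolerance = 1e-12)
  # retained eigenvalues cannot exceed the double-centered trace, which for
  # Euclidean input equals the total sum of squares about the centroid
  expect_lte(sum(ord$eigenvalues),
             sum(scale(pts, scale = FALSE)^2) + 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("axis selection exceeds the cumulative-variance target", {
  ord <- list(coordinates = matrix(rnorm(40), 10, 4),
              eigenvalues = c(5, 3, 1.5, 0.5),
              proportion_explained = c(0.5, 0.3, 0.15, 0.05))
  class(ord) <- "ordination"
  expect_equal(select_top_axes(ord, 0.9)$n_axes, 3)
  expect_equal(select_top_axes(ord, 1.0)$n_axes, 4)
  # monotone in the target
  counts <- vapply(seq(0.05, 1, by = 0.05),
                   function(p) select_top_axes(ord, p)$n_axes, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("two-way PERMANOVA reduces to classical sequential ANOVA", {
  set.seed(21)
  A <- factor(rep(c("a1", "a2"), each = 6))
  B <- factor(rep(c("b1", "b2"), times = 6))
  y <- rnorm(12) + 2 * (A == "a2") + 0.5 * (B == "b2")
  res <- permanova_two_way(matrix(y, ncol = 1), A, B, n_perm = 49, seed = 1)
  ref <- anova(stats::aov(y ~ A * B))
  expect_equal(res$SS[1:4], ref$`Sum Sq`, tolerance = 1e-9)
  expect_equal(res$pseudo_F[1:3], ref$`F value`[1:3], tolerance = 1e-9)
  # ANOVA decomposition identity
  expect_equal(sum(res$SS[1:4]), res$SS[5], tolerance = 1e-9)
})

test_that("PERMANOVA F and R2 match adonis2 on multivariate data", {
  set.seed(4)
  Y <- matrix(rnorm(36), 12, 3)
  A <- factor(rep(c("a1", "a2"), each = 6))
  B <- factor(rep(c("b1", "b2"), times = 6))
  Y[A == "a2", 1] <- Y[A == "a2", 1] + 1.5
  res <- permanova_two_way(Y, A, B, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(Y ~ A * B, method = "euclidean", permutations = 99,
                        by = "terms")
  expect_equal(res$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(res$R2[1:3], ref$R2[1:3], tolerance = 1e-9)
  expect_equal(res$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-9)
})

test_that("an overwhelming effect reaches the permutation floor", {
  set.seed(5)
  A <- factor(rep(c("a1", "a2"), each = 6))
  B <- factor(rep(c("b1", "b2"), times = 6))
  y <- rnorm(12, sd = 1) + 10 * (A == "a2")
  res <- permanova_two_way(matrix(y, ncol = 1), A, B, n_perm = 999, seed = 3)
  # row permutations that recreate the group partition (2 / choose(12, 6)
  # of them) tie the observed F, so the attainable floor sits slightly
  # above 1/(n_perm + 1)
  expect_lte(res$p_value[1], 0.005)
})

test_that("PERMANOVA validates its design", {
  Y <- matrix(rnorm(12), 6, 2)
  expect_error(permanova_two_way(Y, factor(rep("x", 6)),
                                 factor(rep(c("a", "b"), 3)), 9, 1),
               "two levels")
  expect_error(permanova_two_way(Y, factor(c("a", "a", "a", "a", "a", "b")),
                                 factor(c("x", "x", "x", "y", "y", "y")),
                                 9, 1),
               "per cell")
})
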