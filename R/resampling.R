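#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup_x |ECDF_a(x) - ECDF_b(x)|, evaluated at the pooled sample points.
#' Symmetric in its arguments and invariant under any strictly monotone
#' transform applied to both samples.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return D in [0, 1].
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("ks_statistic requires two non-empty samples")
  }
  pooled <- sort(unique(c(sample_a, sample_b)))
  fa <- stats::ecdf(sample_a)(pooled)
  fb <- stats::ecdf(sample_b)(pooled)
  max(abs(fa - fb))
}

new_perm_test_result <- function(statistic_name, observed, p_value, n_perm,
                                 seed, null_values = NULL, extra = list()) {
  structure(c(list(statistic_name = statistic_name, observed = observed,
                   p_value = p_value, n_permutations = n_perm, seed = seed,
                   null_values = null_values), extra),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n  observed = %.6g\n  p = %.6g (%d permutations, seed %d)\n",
              x$statistic_name, x$observed, x$p_value, x$n_permutations,
              x$seed))
  invisible(x)
}

#' Generic permutation p-value for a two-sample statistic
#'
#' Monte-Carlo permutation test with the add-one estimator
#' p = (1 + #\{permuted statistic >= observed\}) / (n_perm + 1), so p is never
#' 0 and never below 1/(n_perm + 1).
#'
#' With `unit = "value"`, individual values are re-assigned to the two
#' groups. With `unit = "block"`, each group is a list of blocks (e.g.
#' replicate populations) whose labels are permuted while block contents stay
#' intact, preserving within-block dependence; the statistic always sees the
#' pooled values of each side.
#'
#' @param group_a,group_b numeric vectors (`unit = "value"`) or lists of
#'   numeric vectors (`unit = "block"`).
#' @param statistic function of two numeric vectors returning a scalar where
#'   larger means more extreme.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer RNG seed.
#' @param unit permutation unit, `"value"` or `"block"`.
#' @param statistic_name label stored in the result.
#' @param store_null keep the permuted statistics in the result?
#' @return a `perm_test_result`.
#' @export
permutation_pvalue <- function(group_a, group_b, statistic = ks_statistic,
                               n_perm = 10000, seed = 1,
                               unit = c("value", "block"),
                               statistic_name = "statistic",
                               store_null = TRUE) {
  unit <- match.arg(unit)
  stopifnot(n_perm >= 1)
  if (unit == "block") {
    stopifnot(is.list(group_a), is.list(group_b))
    blocks <- c(group_a, group_b)
    na <- length(group_a)
    n <- length(blocks)
    obs_a <- unlist(group_a, use.names = FALSE)
    obs_b <- unlist(group_b, use.names = FALSE)
  } else {
    na <- length(group_a)
    n <- na + length(group_b)
    obs_a <- group_a
    obs_b <- group_b
  }
  if (choose(n, na) < 2) {
    stop("fewer than 2 distinct relabelings; nothing to permute")
  }
  observed <- statistic(obs_a, obs_b)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_values <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, na)
    if (unit == "block") {
      statistic(unlist(blocks[idx], use.names = FALSE),
                unlist(blocks[-idx], use.names = FALSE))
    } else {
      pool <- c(obs_a, obs_b)
      statistic(pool[idx], pool[-idx])
    }
  }, numeric(1))
  p <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  new_perm_test_result(statistic_name, observed, p, n_perm, seed,
                       if (store_null) null_values)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = sum |u_f - v_f| / sum (u_f + v_f) over features f; 0 for
#' identical rows, 1 for rows with disjoint support.
#'
#' @param m samples x features matrix of nonnegative values.
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires nonnegative values")
  s <- rowSums(m)
  if (any(s <= 0)) stop("all-zero sample row; Bray-Curtis undefined")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- sum(pmin(m[i, ], m[j, ]))
      d[i, j] <- d[j, i] <- 1 - 2 * w / (s[i] + s[j])
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates scaled by
#' the square roots of the positive eigenvalues. Negative eigenvalues are
#' discarded (no correction). Axis signs follow a deterministic convention:
#' the first coordinate of non-negligible magnitude on each axis is positive.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param tol relative tolerance below which eigenvalues count as zero.
#' @return an `ordination` list: `coordinates` (samples x axes),
#'   `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("pcoa requires a square symmetric distance matrix")
  }
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  vals <- e$values[pos]
  vecs <- e$vectors[, pos, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  for (k in seq_len(ncol(coords))) {
    lead <- which(abs(coords[, k]) > 1e-8)[1]
    if (!is.na(lead) && coords[lead, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 proportion_explained = if (length(vals)) vals / sum(vals)
                                        else numeric(0)),
            class = "ordination")
}

#' Select leading ordination axes by cumulative variance
#'
#' Smallest prefix of axes whose cumulative proportion of explained variance
#' exceeds `min_cum_prop` (all axes if none does, e.g. at `min_cum_prop = 1`).
#'
#' @param ord an `ordination` from [pcoa()].
#' @param min_cum_prop cumulative proportion to exceed (default 0.9).
#' @return list: `coordinates` submatrix, `n_axes`, `cum_prop` achieved.
#' @export
select_top_axes <- function(ord, min_cum_prop = 0.9) {
  stopifnot(min_cum_prop > 0, min_cum_prop <= 1)
  cp <- cumsum(ord$proportion_explained)
  k <- which(cp > min_cum_prop)[1]
  if (is.na(k)) k <- length(cp)
  list(coordinates = ord$coordinates[, seq_len(k), drop = FALSE],
       n_axes = k, cum_prop = cp[k])
}

#' Two-way PERMANOVA on Euclidean coordinates
#'
#' Permutational MANOVA with sequential (Type I) sums of squares for the
#' model `~ A + B + A:B` on Euclidean distances between coordinate rows
#' (equivalently, classical multivariate ANOVA summed over axes).
#' Significance of each term's pseudo-F is assessed by freely permuting
#' sample rows.
#'
#' @param coordinates samples x axes numeric matrix.
#' @param factor_a,factor_b factors (or coercible) of length nrow.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return tibble with one row per term (`A`, `B`, `A:B`) plus residual and
#'   total rows: `term, df, SS, R2, pseudo_F, p_value`.
#' @export
permanova_two_way <- function(coordinates, factor_a, factor_b,
                              n_perm = 10000, seed = 1) {
  Y <- as.matrix(coordinates)
  A <- as.factor(factor_a)
  B <- as.factor(factor_b)
  n <- nrow(Y)
  stopifnot(length(A) == n, length(B) == n)
  if (nlevels(droplevels(A)) < 2 || nlevels(droplevels(B)) < 2) {
    stop("each factor needs at least two levels")
  }
  if (any(table(A, B) < 2)) {
    stop("interaction term needs at least 2 samples per cell")
  }
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H0 <- matrix(1 / n, n, n)
  HA <- hat(stats::model.matrix(~A))
  HAB <- hat(stats::model.matrix(~ A + B))
  HF <- hat(stats::model.matrix(~ A * B))
  dA <- HA - H0
  dB <- HAB - HA
  dI <- HF - HAB
  dR <- diag(n) - HF
  dT <- diag(n) - H0
  df <- c(nlevels(A) - 1, nlevels(B) - 1,
          (nlevels(A) - 1) * (nlevels(B) - 1))
  df_res <- n - nlevels(A) * nlevels(B)
  ss_of <- function(Yp) {
    c(sum(Yp * (dA %*% Yp)), sum(Yp * (dB %*% Yp)), sum(Yp * (dI %*% Yp)),
      sum(Yp * (dR %*% Yp)))
  }
  ss <- ss_of(Y)
  ss_tot <- sum(Y * (dT %*% Y))
  f_of <- function(ss) (ss[1:3] / df) / (ss[4] / df_res)
  f_obs <- f_of(ss)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- numeric(3)
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    exceed <- exceed + (f_of(ss_of(Yp)) >= f_obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  tibble::tibble(
    term = c("A", "B", "A:B", "residual", "total"),
    df = c(df, df_res, n - 1),
    SS = c(ss[1:3], ss[4], ss_tot),
    R2 = c(ss[1:3], ss[4], ss_tot) / ss_tot,
    pseudo_F = c(f_obs, NA, NA),
    p_value = c(p, NA, NA)
  )
}
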