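# Kernel two-sample drift testing: unbiased MMD^2 with an RBF kernel and a
# permutation p-value. The bandwidth comes from the pooled-sample median
# heuristic and is held fixed across permutations so the permutation null is
# exchangeable.

pairwise_sqdist <- function(Z) {
  n2 <- rowSums(Z^2)
  D2 <- outer(n2, n2, "+") - 2 * tcrossprod(Z)
  D2[D2 < 0] <- 0
  D2
}

#' Median-heuristic RBF bandwidth
#'
#' Returns the median of the pairwise Euclidean distances over the pooled
#' sample, excluding the zero self-distances. If the median is zero, falls
#' back to the smallest positive distance; if every distance is zero,
#' returns 1.
#'
#' @param X,Y numeric matrices (or vectors) with matching column count.
#' @return a positive scalar bandwidth.
#' @export
median_heuristic_bandwidth <- function(X, Y = NULL) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (!is.null(Y)) {
    if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
    X <- rbind(X, Y)
  }
  if (nrow(X) < 2) stop("pooled sample size must be at least 2", call. = FALSE)
  d <- as.vector(stats::dist(X))
  med <- stats::median(d)
  if (med > 0) return(med)
  pos <- d[d > 0]
  if (length(pos) > 0) return(min(pos))
  1
}

rbf_kernel_from_sqdist <- function(D2, bandwidth) {
  exp(-D2 / (2 * bandwidth^2))
}

mmd2_from_kernel <- function(K, z) {
  # z: logical membership of the pooled rows in sample X (diag(K) must be 1)
  n <- sum(z); m <- sum(!z)
  zi <- as.numeric(z)
  Kz <- K %*% zi
  s_xx <- sum(zi * Kz) - n
  k1 <- sum(Kz)                      # z' K 1
  tot <- sum(K)
  s_yy <- tot - 2 * k1 + sum(zi * Kz) - m
  s_xy <- k1 - sum(zi * Kz)
  s_xx / (n * (n - 1)) + s_yy / (m * (m - 1)) - 2 * s_xy / (n * m)
}

#' Unbiased squared maximum mean discrepancy
#'
#' Computes the unbiased U-statistic estimate of MMD^2 between samples `X`
#' and `Y` under the RBF kernel
#' `k(a, b) = exp(-||a - b||^2 / (2 * bandwidth^2))`:
#' the two within-sample mean similarities (off-diagonal) minus twice the
#' between-sample mean similarity. The estimate can be negative.
#'
#' @param X `n x d` matrix, `n >= 2`.
#' @param Y `m x d` matrix, `m >= 2`.
#' @param bandwidth positive RBF bandwidth (default: median heuristic on the
#'   pooled sample).
#' @return scalar unbiased MMD^2 estimate.
#' @export
mmd2_unbiased <- function(X, Y, bandwidth = median_heuristic_bandwidth(X, Y)) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(X) < 2 || nrow(Y) < 2) {
    stop("both samples must contain at least 2 rows", call. = FALSE)
  }
  stopifnot(ncol(X) == ncol(Y), bandwidth > 0)
  Z <- rbind(X, Y)
  K <- rbf_kernel_from_sqdist(pairwise_sqdist(Z), bandwidth)
  mmd2_from_kernel(K, c(rep(TRUE, nrow(X)), rep(FALSE, nrow(Y))))
}

#' MMD permutation test for distributional drift
#'
#' The observed unbiased MMD^2 is compared against its permutation null:
#' group labels are shuffled across the pooled sample (preserving group
#' sizes) and the statistic recomputed with the same kernel and bandwidth.
#' The p-value uses the add-one convention
#' `p = (1 + #\{permuted >= observed\}) / (n_permutations + 1)`, so
#' `p >= 1/(n_permutations + 1)` always.
#'
#' @param X source feature matrix (`n x d`, `n >= 2`).
#' @param Y target feature matrix (`m x d`, `m >= 2`).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param bandwidth RBF bandwidth; default median heuristic on the pooled
#'   sample, held fixed across permutations.
#' @return an `mmd_result`: list with `statistic`, `p_value`, `n_source`,
#'   `n_target`, `n_permutations`, `bandwidth`, `seed`, and a summary of the
#'   permutation distribution (`perm_mean`, `perm_sd`, `perm_q95`).
#' @export
mmd_permutation_test <- function(X, Y, n_permutations = 1000L, seed = 1L,
                                 bandwidth = NULL) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(X) < 2 || nrow(Y) < 2) {
    stop("both samples must contain at least 2 rows", call. = FALSE)
  }
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)
  n <- nrow(X); m <- nrow(Y); N <- n + m
  Z <- rbind(X, Y)
  D2 <- pairwise_sqdist(Z)
  degenerate <- all(D2 < 1e-24)
  if (is.null(bandwidth)) bandwidth <- median_heuristic_bandwidth(Z)
  if (degenerate) {
    warning("all pooled points are identical; returning p = 1")
    return(structure(list(statistic = 0, p_value = 1, n_source = n,
                          n_target = m, n_permutations = as.integer(n_permutations),
                          bandwidth = bandwidth, seed = as.integer(seed),
                          perm_mean = 0, perm_sd = 0, perm_q95 = 0),
                     class = "mmd_result"))
  }
  K <- rbf_kernel_from_sqdist(D2, bandwidth)
  obs <- mmd2_from_kernel(K, c(rep(TRUE, n), rep(FALSE, m)))

  # all permutations at once: membership matrix Zb (N x B), one gemm
  B <- as.integer(n_permutations)
  Zb <- with_stream(seed, {
    M <- matrix(0, N, B)
    for (b in seq_len(B)) M[sample.int(N, n), b] <- 1
    M
  })
  KZ <- K %*% Zb
  zKz <- colSums(Zb * KZ)
  zK1 <- colSums(KZ)
  tot <- sum(K)
  s_xx <- zKz - n
  s_yy <- tot - 2 * zK1 + zKz - m
  s_xy <- zK1 - zKz
  perm <- s_xx / (n * (n - 1)) + s_yy / (m * (m - 1)) - 2 * s_xy / (n * m)

  p <- (1 + sum(perm >= obs)) / (B + 1)
  structure(list(statistic = obs, p_value = p, n_source = n, n_target = m,
                 n_permutations = B, bandwidth = bandwidth,
                 seed = as.integer(seed),
                 perm_mean = mean(perm), perm_sd = stats::sd(perm),
                 perm_q95 = unname(stats::quantile(perm, 0.95))),
            class = "mmd_result")
}

#' @export
print.mmd_result <- function(x, ...) {
  cat(sprintf("<mmd_result> MMD^2 = %.4g, p = %.4g (n = %d, m = %d, %d permutations, bandwidth = %.3g)\n",
              x$statistic, x$p_value, x$n_source, x$n_target,
              x$n_permutations, x$bandwidth))
  invisible(x)
}

#' Run MMD tests on a batch of source/target feature pairs
#'
#' @param pairs list of `list(X = , Y = )` feature-matrix pairs.
#' @param n_permutations,seed passed to [mmd_permutation_test()]; each pair
#'   gets its own derived seed.
#' @return a list of `mmd_result` objects.
#' @export
mmd_batch <- function(pairs, n_permutations = 1000L, seed = 1L) {
  lapply(seq_along(pairs), function(i) {
    mmd_permutation_test(pairs[[i]]$X, pairs[[i]]$Y,
                         n_permutations = n_permutations,
                         seed = derive_seed(seed, "batch", i))
  })
}
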