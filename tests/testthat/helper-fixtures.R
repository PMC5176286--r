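# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; no data files are read.

# Random stack of N symmetric D x D matrices with i.i.d. Gaussian entries
# on the upper triangle (incl. diagonal).
random_stack <- function(N, D, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(seq_len(N), function(n) {
    A <- matrix(rnorm(D * D, sd = sd), D)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    A
  })
  as_connectivity_stack(mats)
}

# Rank-one variability: X_n = s_n * Bstar for a fixed unit-norm symmetric
# Bstar and mixed-sign scores with zero mean.
rank_one_stack <- function(scores, D = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(D * D), D)
  Bstar <- (A + t(A)) / 2
  Bstar <- Bstar / sqrt(sum(Bstar^2))
  stack <- as_connectivity_stack(lapply(scores, function(s) s * Bstar))
  list(stack = stack, Bstar = Bstar)
}

# Random weight matrix in the disjoint nonnegative set with unit-norm
# columns, every module holding at least min_size nodes.
random_omega_plus <- function(D, K, min_size = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    grp <- sample.int(K, D, replace = TRUE)
    if (all(tabulate(grp, K) >= min_size)) break
  }
  W <- matrix(0, D, K)
  W[cbind(seq_len(D), grp)] <- runif(D, 0.5, 1.5)
  normalize_columns(W)
}

# Random symmetric K x K matrix with unit Frobenius norm; resampled until
# well-conditioned so W G W' has rank exactly K.
random_unit_g <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    A <- matrix(rnorm(K * K), K)
    G <- (A + t(A)) / 2
    G <- G / sqrt(sum(G^2))
    if (min(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values)) > 0.05)
      return(G)
  }
}

# The noiseless 4-node family with a closed-form solution: scores (1,-2,1),
# one single-node module and one two-node module, pure inter-module G.
toy_family <- function() {
  W <- matrix(0, 4, 2)
  W[1, 1] <- 1
  W[3:4, 2] <- 1 / sqrt(2)
  G <- matrix(c(0, 1, 1, 0) / sqrt(2), 2)
  B <- W %*% G %*% t(W)
  s <- c(1, -2, 1)
  stack <- as_connectivity_stack(lapply(s, function(si) si * B))
  list(stack = stack, W = W, G = G, B = B, scores = s)
}

# Brute-force Frobenius-nearest point in the disjoint nonnegative set:
# enumerate every per-row support choice (each column, with the value
# clipped at zero, or an all-zero row) and keep the global minimizer.
# Independent of the row-wise closed form used by the package.
oracle_project_omega_plus <- function(A) {
  D <- nrow(A)
  K <- ncol(A)
  best <- NULL
  best_d <- Inf
  choices <- rep(list(0:K), D)
  grid <- do.call(expand.grid, choices)
  for (g in seq_len(nrow(grid))) {
    Z <- matrix(0, D, K)
    for (i in seq_len(D)) {
      k <- grid[g, i]
      if (k > 0) Z[i, k] <- max(A[i, k], 0)
    }
    d <- sum((A - Z)^2)
    if (d < best_d - 1e-15) {
      best_d <- d
      best <- Z
    }
  }
  best
}

# Numeric maximization of w1' C w2 over orthonormal pairs, independent of
# the closed form: unconstrained parameterization (a, b) -> (w1, w2) via
# normalization and Gram-Schmidt, optimized with BFGS from several starts.
oracle_max_bilinear <- function(C, n_starts = 12, seed = 1) {
  D <- nrow(C)
  set.seed(seed)
  par_to_pair <- function(p) {
    a <- p[1:D]
    b <- p[(D + 1):(2 * D)]
    w1 <- a / sqrt(sum(a^2))
    b <- b - sum(b * w1) * w1
    w2 <- b / sqrt(sum(b^2))
    list(w1 = w1, w2 = w2)
  }
  neg_obj <- function(p) {
    pr <- par_to_pair(p)
    -drop(crossprod(pr$w1, C %*% pr$w2))
  }
  best <- -Inf
  for (s in seq_len(n_starts)) {
    p0 <- rnorm(2 * D)
    res <- tryCatch(
      optim(p0, neg_obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res)) best <- max(best, -res$value)
  }
  best
}

# Invariant bundle asserted on every fitted modular component.
expect_mcf_invariants <- function(fit, K) {
  expect_true(all(fit$W >= 0))
  expect_true(all(rowSums(fit$W > 0) <= 1))
  expect_lt(max(abs(crossprod(fit$W) - diag(K))), 1e-8)
  expect_lt(abs(sqrt(sum(fit$G^2)) - 1), 1e-8)
  expect_lt(max(abs(fit$G - t(fit$G))), 1e-8)
  expect_lt(abs(sqrt(sum(fit$B^2)) - 1), 1e-8)
  expect_lt(max(abs(fit$B - t(fit$B))), 1e-10)
  expect_true(all(diff(fit$objective_trace) >= -1e-8 * max(fit$objective_trace)))
  expect_gte(fit$objective,
             fit$init_objective * (1 - 1e-10) - 1e-12)
}
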