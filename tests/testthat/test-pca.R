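# Unconstrained eigenconnectivity analysis: maximization, deflation,
# spectrum, low-rank truncation.

test_that("rank-one variability is recovered exactly up to sign", {
  fam <- rank_one_stack(c(1.5, -2, 0.5, 1, -1), D = 4, seed = 3)
  cs <- center_stack(fam$stack)
  fit <- pca_first_component(cs)
  err <- min(sqrt(sum((fit$B - fam$Bstar)^2)),
             sqrt(sum((fit$B + fam$Bstar)^2)))
  expect_lt(err, 1e-8)
  expect_lt(max(abs(fit$B - t(fit$B))), 1e-10)
})

test_that("the leading component matches the dense vectorized second-moment oracle", {
  for (seed in 1:10) {
    D <- sample(3:6, 1)
    st <- random_stack(20, D, seed = seed)
    cs <- center_stack(st)
    fit <- pca_first_component(cs)
    # independent oracle: top eigenvector of the D^2 x D^2 second moment
    S <- crossprod(cs$data)
    b <- eigen(S, symmetric = TRUE)$vectors[, 1]
    Bo <- matrix(b, D, D)
    err <- min(sqrt(sum((fit$B - Bo)^2)), sqrt(sum((fit$B + Bo)^2)))
    expect_lt(err, 1e-8)
    expect_equal(fit$scores, drop(cs$data %*% as.numeric(fit$B)))
  }
})

test_that("the Gram route agrees with the direct route", {
  st <- random_stack(5, 6, seed = 21)  # D^2 = 36 > N = 5 -> Gram route
  cs <- center_stack(st)
  fit <- pca_first_component(cs)
  S <- crossprod(cs$data)
  b <- eigen(S, symmetric = TRUE)$vectors[, 1]
  Bo <- matrix(b, 6, 6)
  err <- min(sqrt(sum((fit$B - Bo)^2)), sqrt(sum((fit$B + Bo)^2)))
  expect_lt(err, 1e-8)
})

test_that("multi-component extraction equals explicit subtract-and-refit deflation", {
  st <- random_stack(30, 4, seed = 13)
  cs <- center_stack(st)
  comps <- pca_components(cs, 3)
  # oracle: recursive rank-one deflation, refitting from scratch each time
  res <- cs
  for (m in 1:3) {
    fit <- pca_first_component(res)
    err <- min(sqrt(sum((comps[[m]]$B - fit$B)^2)),
               sqrt(sum((comps[[m]]$B + fit$B)^2)))
    expect_lt(err, 1e-8)
    res$data <- res$data - fit$scores %*% t(as.numeric(fit$B))
  }
  # mutual orthogonality and nonincreasing variance
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(sum(comps[[i]]$B * comps[[j]]$B)), 1e-8)
  }
  ev <- vapply(comps, `[[`, numeric(1), "explained_variance")
  expect_true(all(diff(ev) <= 1e-10))
  expect_equal(comps[[1]]$B, pca_first_component(cs)$B)
})

test_that("two-direction synthetic data spans the planted basis", {
  sim <- simulate_modular_pair(60, noise_sd = 0, seed = 5)
  cs <- center_stack(sim$stack)
  comps <- pca_components(cs, 2)
  Btrue <- cbind(as.numeric(sim$truth$B_true[[1]]),
                 as.numeric(sim$truth$B_true[[2]]))
  Bhat <- cbind(as.numeric(comps[[1]]$B), as.numeric(comps[[2]]$B))
  # principal angles between the two 2-D subspaces
  sv <- svd(crossprod(qr.Q(qr(Btrue)), qr.Q(qr(Bhat))))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("total variance is conserved over a full component set", {
  st <- random_stack(40, 3, seed = 8)   # rank D(D+1)/2 = 6
  cs <- center_stack(st)
  comps <- pca_components(cs, 6)
  expect_length(comps, 6)
  expect_equal(sum(vapply(comps, `[[`, numeric(1), "explained_variance")),
               sum(cs$data^2) / 40, tolerance = 1e-10)
})

test_that("requesting components beyond the rank truncates with a warning", {
  fam <- rank_one_stack(c(1, -1, 2, -2), D = 3, seed = 2)
  cs <- center_stack(fam$stack)
  expect_warning(comps <- pca_components(cs, 3), "exhausted")
  expect_length(comps, 1)
})

test_that("degenerate all-zero variability is an explicit error", {
  M <- diag(3)
  st <- as_connectivity_stack(list(M, M, M))
  cs <- center_stack(st)
  expect_error(pca_first_component(cs), "degenerate")
})

test_that("repeated runs on identical input give bitwise-identical components", {
  st <- random_stack(15, 4, seed = 99)
  cs <- center_stack(st)
  f1 <- pca_first_component(cs)
  f2 <- pca_first_component(cs)
  expect_identical(f1$B, f2$B)
  i <- which.max(abs(f1$B))
  expect_gt(f1$B[i], 0)
})

test_that("the eigen-spectrum decomposes the squared norm of B", {
  W <- random_omega_plus(6, 2, seed = 4)
  G <- random_unit_g(2, seed = 4)
  B <- W %*% G %*% t(W)
  sp <- eigen_spectrum(B, order = "magnitude")
  expect_equal(sum(abs(sp$eigenvalue) > 1e-10), 2)
  expect_equal(sp$squared_cumulative[2], 1, tolerance = 1e-10)
  st <- random_stack(10, 5, seed = 6)
  sp2 <- eigen_spectrum(pca_first_component(center_stack(st)))
  expect_equal(sp2$squared_cumulative[5], 1, tolerance = 1e-12)
  expect_true(all(diff(sp2$squared_cumulative) >= -1e-15))
  expect_true(all(diff(sp2$eigenvalue) <= 1e-12))
  expect_error(eigen_spectrum(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("low-rank eigen-truncation keeps the largest-magnitude eigenpairs", {
  lr <- low_rank_eigen(diag(c(3, -2, 0.1)), 2)
  expect_equal(sort(lr$Q), c(-2, 3))
  expect_equal(abs(lr$U), cbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12)

  set.seed(31)
  A <- matrix(rnorm(100), 10)
  B <- (A + t(A)) / 2
  for (K in c(2, 5)) {
    lr <- low_rank_eigen(B, K)
    approx <- lr$U %*% diag(lr$Q, K) %*% t(lr$U)
    e <- eigen(B, symmetric = TRUE)
    discarded <- sort(abs(e$values), decreasing = TRUE)[-(1:K)]
    # Eckart-Young: squared truncation error = sum of discarded squares
    expect_equal(sum((B - approx)^2), sum(discarded^2), tolerance = 1e-10)
    expect_equal(sort(abs(lr$Q), decreasing = TRUE),
                 sort(abs(e$values), decreasing = TRUE)[1:K],
                 tolerance = 1e-12)
  }
  expect_error(low_rank_eigen(diag(3), 3), "smaller")
})
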