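# Constrained principal component solver: single component, deflation,
# adjusted variance, scores.

test_that("the noiseless 4-node family has the closed-form solution", {
  fam <- toy_family()
  cs <- center_stack(fam$stack)
  fit <- mcf_fit_component(cs, 2, solver_config(seed = 42))
  # scores (1,-2,1) are already centered, so the objective is 1+4+1 = 6
  expect_equal(fit$objective, 6, tolerance = 1e-10)
  expect_lt(estimation_error(fam$B, fit$B), 1e-6)
  expect_mcf_invariants(fit, 2)
})

test_that("component scores are trace inner products", {
  W <- random_omega_plus(5, 2, seed = 15)
  G <- random_unit_g(2, seed = 15)
  B <- W %*% G %*% t(W)
  st <- as_connectivity_stack(list(3 * B + 1, 3 * B - 1, -6 * B))
  cs <- center_stack(st)
  # centered matrices are (1+const, ...) multiples of B plus a constant
  # matrix; verify against the elementwise oracle
  oracle <- vapply(1:3, function(n) sum(B * stack_matrix(cs, n)), numeric(1))
  expect_equal(component_scores(cs, B), oracle, tolerance = 1e-12)
  # X~ = 3B gives score 3; a direction orthogonal to the data gives 0
  st2 <- as_connectivity_stack(list(3 * B, -3 * B))
  expect_equal(component_scores(center_stack(st2), B), c(3, -3),
               tolerance = 1e-12)
  # a unit direction orthogonal to B scores exactly zero
  set.seed(16)
  Q0 <- matrix(rnorm(25), 5)
  Q0 <- (Q0 + t(Q0)) / 2
  Q <- Q0 - sum(Q0 * B) * B
  Q <- Q / sqrt(sum(Q^2))
  expect_lt(max(abs(component_scores(center_stack(st2), Q))), 1e-10)
  expect_error(component_scores(cs, 2 * B), "unit Frobenius")
})

test_that("solver invariants hold on random data and the trace is monotone", {
  for (seed in c(3, 19)) {
    st <- random_stack(30, 8, sd = 1, seed = seed)
    cs <- center_stack(st)
    cfg <- solver_config(seed = seed)
    B_pca <- pca_first_component(cs)$B
    init <- stepwise_factorize(B_pca, 2, cfg)
    fit <- mcf_fit_component(cs, 2, cfg, init = init)
    expect_mcf_invariants(fit, 2)
    # final objective at least the stepwise initializer's
    G0 <- init$G / sqrt(sum(init$G^2))
    B0 <- init$W %*% G0 %*% t(init$W)
    expect_gte(fit$objective, sum(component_scores(cs, B0)^2) - 1e-8)
  }
})

test_that("a fit is deterministic given data, K and seed", {
  sim <- simulate_modular_component(0.3, 150, seed = 8)
  cs <- center_stack(sim$stack)
  f1 <- mcf_fit_component(cs, 2, solver_config(seed = 4))
  f2 <- mcf_fit_component(cs, 2, solver_config(seed = 4))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$scores, f2$scores)
})

test_that("invalid K and constraint-violating inits are rejected", {
  st <- random_stack(10, 4, seed = 2)
  cs <- center_stack(st)
  expect_error(mcf_fit_component(cs, 4, solver_config(seed = 1)), "K < D")
  badW <- matrix(1 / 2, 4, 2)  # overlapping supports
  expect_error(
    mcf_fit_component(cs, 2, solver_config(seed = 1),
                      init = list(W = badW, G = diag(2) / sqrt(2))),
    "disjoint")
})

test_that("multi-component fits deflate energy and match the single fit at M = 1", {
  sim <- simulate_modular_pair(150, seed = 12)
  cs <- center_stack(sim$stack)
  cfg <- solver_config(n_restarts = 1, seed = 6)
  model <- mcf_fit(cs, K = 2, M = 2, config = cfg)
  expect_s3_class(model, "mcf_model")
  expect_length(model$components, 2)
  for (co in model$components) expect_mcf_invariants(co, 2)
  # residual energy after removing both components is below the input energy
  resid <- cs$data
  for (co in model$components) {
    resid <- resid - co$scores %*% t(as.numeric(co$B))
  }
  expect_lt(sum(resid^2), sum(cs$data^2))
  expect_lte(max(model$adjusted$cumulative_adjusted),
             model$total_variance * (1 + 1e-6))

  # M = 1 with one restart reproduces the component-level fit at the same
  # derived seed and initialization
  m1 <- mcf_fit(cs, K = 2, M = 1, config = cfg)
  cfg1 <- cfg
  cfg1$seed <- modconn:::derive_seeds(cfg$seed, 1)[[1]]
  init <- stepwise_factorize(pca_first_component(cs)$B, 2, cfg1)
  single <- mcf_fit_component(cs, 2, cfg1, init = init)
  expect_equal(m1$components[[1]]$B, single$B, tolerance = 1e-12)
  expect_equal(m1$components[[1]]$objective, single$objective)
})

test_that("restarts keep the best objective", {
  sim <- simulate_modular_component(0.5, 120, seed = 14)
  cs <- center_stack(sim$stack)
  m5 <- mcf_fit(cs, 2, 1, solver_config(n_restarts = 5, seed = 10))
  m1 <- mcf_fit(cs, 2, 1, solver_config(n_restarts = 1, seed = 10))
  expect_gte(m5$components[[1]]$objective,
             m1$components[[1]]$objective - 1e-9)
})

test_that("adjusted variance equals raw variance for an orthogonal basis", {
  set.seed(25)
  W <- matrix(0, 8, 2)
  W[1:3, 1] <- runif(3, 0.5, 1.5)
  W[4:6, 2] <- runif(3, 0.5, 1.5)
  W <- normalize_columns(W)
  G1 <- random_unit_g(2, seed = 25)
  B1 <- W %*% G1 %*% t(W)
  # second basis on nodes 7-8: disjoint support, exactly orthogonal to B1
  W2 <- matrix(0, 8, 2)
  W2[7, 1] <- 1
  W2[8, 2] <- 1
  B2 <- W2 %*% matrix(c(0, 1, 1, 0) / sqrt(2), 2) %*% t(W2)
  st <- random_stack(20, 8, seed = 26)
  cs <- center_stack(st)
  comps <- list(list(B = B1, scores = component_scores(cs, B1)),
                list(B = B2, scores = component_scores(cs, B2)))
  adj <- adjusted_explained_variance(comps, cs)
  expect_equal(adj$adjusted_variance, adj$variance, tolerance = 1e-10)
  # single component: adjusted variance is just the score variance
  adj1 <- adjusted_explained_variance(comps[1], cs)
  expect_equal(adj1$adjusted_variance,
               sum(comps[[1]]$scores^2) / 20, tolerance = 1e-12)
})

test_that("adjusted variance matches a QR-factorization oracle for oblique bases", {
  set.seed(27)
  D <- 6
  A1 <- matrix(rnorm(D * D), D)
  B1 <- (A1 + t(A1)) / 2
  B1 <- B1 / sqrt(sum(B1^2))
  B2 <- 0.6 * B1 + 0.4 * (function(A) {
    S <- (A + t(A)) / 2
    S / sqrt(sum(S^2))
  })(matrix(rnorm(D * D), D))
  B2 <- B2 / sqrt(sum(B2^2))
  st <- random_stack(25, D, seed = 28)
  cs <- center_stack(st)
  comps <- list(list(B = B1, scores = component_scores(cs, B1)),
                list(B = B2, scores = component_scores(cs, B2)))
  adj <- adjusted_explained_variance(comps, cs)
  # oracle: thin QR of the basis columns; energy of R %*% S per row
  Bmat <- cbind(as.numeric(B1), as.numeric(B2))
  S <- rbind(comps[[1]]$scores, comps[[2]]$scores)
  qrB <- qr(Bmat)
  Rm <- qr.R(qrB)
  St <- Rm %*% S
  expect_equal(adj$adjusted_variance, rowSums(St^2) / 25, tolerance = 1e-10)
  # a linearly dependent third basis matrix is dropped with a warning
  comps3 <- c(comps, list(list(B = B1, scores = comps[[1]]$scores)))
  expect_warning(adj3 <- adjusted_explained_variance(comps3, cs),
                 "dependent")
  expect_equal(nrow(adj3), 2)
})

test_that("tidy and glance expose weights and fit summaries", {
  fam <- toy_family()
  cs <- center_stack(fam$stack)
  model <- mcf_fit(cs, 2, 1, solver_config(n_restarts = 2, seed = 5))
  td <- tidy(model)
  expect_true(all(c("component", "node_id", "module", "weight") %in%
                  names(td)))
  expect_true(all(td$weight > 0))
  gl <- glance(model)
  expect_equal(gl$M, 1)
  expect_true(gl$prop_explained <= 1 + 1e-9)
  gc <- glance(model$components[[1]])
  expect_true(is.logical(gc$converged))
})
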