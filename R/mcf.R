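#' Solver configuration
#'
#' Collects the tunable parameters shared by the iterative solvers.
#'
#' @param eta0 initial gradient stepsize (reset at every outer iteration).
#' @param alpha Armijo sufficient-ascent constant in (0, 1).
#' @param beta backtracking shrink factor in (0, 1).
#' @param eps_stepwise rotation-convergence tolerance of the stepwise
#'   factorizer.
#' @param eps_main convergence tolerance `||W' W_old - I||_F` of the main
#'   solver.
#' @param max_outer_iters cap on outer alternating iterations.
#' @param max_backtracks cap on stepsize halvings per outer iteration.
#' @param n_restarts number of random initializations kept when fitting a
#'   component (the best objective wins).
#' @param seed optional integer seed making every fit deterministic.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(eta0 = 0.01, alpha = 1e-4, beta = 0.5,
                          eps_stepwise = 1e-12, eps_main = 1e-6,
                          max_outer_iters = 500L, max_backtracks = 50L,
                          n_restarts = 20L, seed = NULL) {
  stopifnot(eta0 > 0, alpha > 0, alpha < 1, beta > 0, beta < 1,
            max_outer_iters >= 1, max_backtracks >= 1, n_restarts >= 1)
  structure(list(eta0 = eta0, alpha = alpha, beta = beta,
                 eps_stepwise = eps_stepwise, eps_main = eps_main,
                 max_outer_iters = as.integer(max_outer_iters),
                 max_backtracks = as.integer(max_backtracks),
                 n_restarts = as.integer(n_restarts), seed = seed),
            class = "solver_config")
}

#' Fit one modular eigenconnectivity component
#'
#' Solves the constrained principal component problem: maximize
#' `sum_n (tr[W G' W' X~_n])^2` over module weight matrices W (disjoint,
#' nonnegative, unit orthonormal columns) and a unit-Frobenius-norm
#' module-level matrix G. The solver alternates (i) an auxiliary unit vector
#' `r` proportional to the current scores, (ii) the weighted data matrix
#' `C = sum_n r_n X~_n`, and (iii) a single projected-gradient ascent step
#' on `f(W) = ||W' C W||^2` along the Stiefel tangent direction, with
#' Armijo backtracking; G is then the analytic optimum `W'CW / ||W'CW||`.
#' Initialization is the stepwise factorization of the leading PCA
#' eigenconnectivity (or a user-supplied `init`). The objective trace is
#' nondecreasing.
#'
#' @param cs a `centered_stack`.
#' @param K number of modules, `2 <= K < D`.
#' @param config a [solver_config()].
#' @param init optional list with elements `W` and `G` satisfying the
#'   constraints (e.g. from [stepwise_factorize()]).
#' @return an object of class `mcf_component`: `W`, `G`, `B = W G W'`
#'   (unit norm), `scores`, `objective` (`sum(scores^2)`),
#'   `objective_trace`, `init_objective`, `converged`, `iterations`.
#' @export
mcf_fit_component <- function(cs, K, config = solver_config(), init = NULL) {
  stopifnot(inherits(cs, "centered_stack"))
  D <- cs$D
  if (K >= D || K < 1) stop("need 1 <= K < D", call. = FALSE)
  Xmat <- cs$data
  if (sum(Xmat^2) == 0) stop("degenerate stack: no variability",
                             call. = FALSE)
  if (is.null(init)) {
    B_pca <- pca_first_component(cs)$B
    init <- stepwise_factorize(B_pca, K, config)
  }
  W <- init$W
  G <- init$G
  check_weight_init(W, G, D, K)
  G <- G / frob(G)
  G <- (G + t(G)) / 2

  h <- stack_half(cs)
  score_of <- function(W, G) half_scores(h, W %*% G %*% t(W))
  s <- score_of(W, G)
  init_objective <- sum(s^2)
  trace <- init_objective
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_outer_iters) {
    iter <- iter + 1L
    ns <- sqrt(sum(s^2))
    if (ns == 0) stop("degenerate component: all scores zero", call. = FALSE)
    r <- s / ns
    C <- half_weighted_sum(h, r)
    W_old <- W
    W <- ascend_step(W, C, config)
    WCW <- crossprod(W, C %*% W)
    nG <- frob(WCW)
    if (nG == 0) stop("degenerate component: W' C W vanished", call. = FALSE)
    G <- (WCW + t(WCW)) / (2 * nG)
    s <- score_of(W, G)
    trace <- c(trace, sum(s^2))
    if (frob(crossprod(W, W_old) - diag(K)) < config$eps_main) {
      converged <- TRUE
      break
    }
  }
  finalize_component(W, G, s, trace, init_objective, converged, iter, cs)
}

# One projected-gradient ascent step on f(W) = ||W'CW||^2 with Armijo
# backtracking; returns W unchanged when no improving step is found.
ascend_step <- function(W, C, config) {
  CW <- C %*% W
  WCW <- crossprod(W, CW)
  fW <- sum(WCW^2)
  grad <- 4 * CW %*% WCW
  delta <- grad - W %*% crossprod(grad, W)   # Stiefel tangent direction
  eta <- config$eta0
  best_W <- NULL
  best_f <- fW
  for (bt in seq_len(config$max_backtracks)) {
    cand <- project_omega_plus(W + eta * delta)
    eta <- eta * config$beta
    if (any(colSums(cand^2) == 0)) next     # lost a module: shrink stepsize
    cand <- normalize_columns(cand)
    WCWc <- crossprod(cand, C %*% cand)
    fc <- sum(WCWc^2)
    if (fc >= fW + config$alpha * sum(grad * (cand - W))) return(cand)
    if (fc > best_f) {
      best_f <- fc
      best_W <- cand
    }
  }
  if (!is.null(best_W)) best_W else W
}

check_weight_init <- function(W, G, D, K) {
  if (!is.matrix(W) || nrow(W) != D || ncol(W) != K) {
    stop("init W has wrong dimensions", call. = FALSE)
  }
  if (!in_omega_plus(W)) stop("init W violates disjoint nonnegativity",
                              call. = FALSE)
  if (max(abs(crossprod(W) - diag(K))) > 1e-8) {
    stop("init W columns not orthonormal", call. = FALSE)
  }
  if (!is.matrix(G) || any(dim(G) != K)) stop("init G has wrong dimensions",
                                              call. = FALSE)
}

# Fix the global sign (maximize the summed squares of G's positive entries)
# and the module order (decreasing |g_kk|, ties by first support node), then
# assemble the component object.
finalize_component <- function(W, G, s, trace, init_objective, converged,
                               iter, cs) {
  pos_energy <- function(M) sum(pmax(M, 0)^2)
  if (pos_energy(-G) > pos_energy(G)) {
    G <- -G
    s <- -s
  }
  first_support <- apply(W, 2, function(w) {
    i <- which(w != 0)
    if (length(i)) min(i) else nrow(W) + 1L
  })
  ord <- order(-abs(diag(G)), first_support)
  W <- W[, ord, drop = FALSE]
  G <- G[ord, ord, drop = FALSE]
  B <- W %*% G %*% t(W)
  if (frob(G) > 1e8 * min(svd(G)$d)) {
    warning("module-level matrix G is near-singular", call. = FALSE)
  }
  rownames(W) <- cs$node_labels
  colnames(W) <- paste0("module", seq_len(ncol(W)))
  dimnames(G) <- list(colnames(W), colnames(W))
  structure(
    list(W = W, G = G, B = B, scores = s, objective = sum(s^2),
         objective_trace = trace, init_objective = init_objective,
         converged = converged, iterations = iter,
         K = ncol(W), node_labels = cs$node_labels,
         subject_ids = cs$subject_ids),
    class = "mcf_component")
}

#' Fit a multi-component modular factorization model
#'
#' Extracts `M` components by deflation: after each fitted component the
#' explained part `s_n * B` is subtracted from every centered matrix before
#' the next component is fitted. Each component is the best of
#' `config$n_restarts` runs (restarts differ in the random rotation used to
#' initialize the stepwise factorizer) by final objective. Adjusted
#' explained variances (Gram-Schmidt-orthogonalized basis) are attached.
#'
#' @param cs a `centered_stack`.
#' @param K number of modules per component.
#' @param M number of components.
#' @param config a [solver_config()].
#' @return an object of class `mcf_model`: `components` (list of
#'   `mcf_component`), `adjusted` (tibble from
#'   [adjusted_explained_variance()]), `total_variance`, `K`, `M`, `config`.
#' @export
mcf_fit <- function(cs, K, M = 1L, config = solver_config()) {
  stopifnot(inherits(cs, "centered_stack"), M >= 1)
  seeds <- derive_seeds(config$seed, M * config$n_restarts)
  residual <- cs
  components <- vector("list", M)
  for (m in seq_len(M)) {
    B_pca <- pca_first_component(residual)$B
    best <- NULL
    for (rep in seq_len(config$n_restarts)) {
      cfg <- config
      cfg$seed <- seeds[[(m - 1L) * config$n_restarts + rep]]
      fit <- tryCatch(
        mcf_fit_component(residual, K, cfg,
                          init = stepwise_factorize(B_pca, K, cfg)),
        error = function(e) {
          stop(sprintf("component %d, restart %d: %s", m, rep,
                       conditionMessage(e)), call. = FALSE)
        })
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
    components[[m]] <- best
    residual$data <- residual$data - best$scores %*% t(vec(best$B))
  }
  structure(
    list(components = components,
         adjusted = adjusted_explained_variance(components, cs),
         total_variance = total_variance(cs),
         K = K, M = M, config = config),
    class = "mcf_model")
}

#' Scores of a stack along a unit-norm basis matrix
#'
#' `s_n = tr[B' X~_n]`, the coefficient of matrix n along the
#' eigenconnectivity direction B.
#'
#' @param cs a `centered_stack`.
#' @param B unit-Frobenius-norm D x D matrix.
#' @return length-N numeric vector.
#' @export
component_scores <- function(cs, B) {
  stopifnot(inherits(cs, "centered_stack"))
  B <- as.matrix(B)
  if (abs(frob(B) - 1) > 1e-6) stop("B must have unit Frobenius norm",
                                    call. = FALSE)
  drop(cs$data %*% vec(B))
}

#' Adjusted explained variance of a component set
#'
#' Component basis matrices extracted by deflation are not necessarily
#' mutually orthogonal, so per-component score variances cannot simply be
#' summed. The basis is orthonormalized by Gram-Schmidt and the scores are
#' re-expressed in the orthonormal basis (leaving the reconstruction
#' `sum_m s_mn B_m` unchanged); the adjusted variances of the orthonormal
#' coordinates then add up to the variance the components jointly explain.
#' A basis matrix that is linearly dependent on its predecessors (pivot
#' below `1e-10`) is dropped with a warning.
#'
#' @param components list of fitted components (each with elements `B` and
#'   `scores`), e.g. from [mcf_fit()] or [ocf_fit()].
#' @param cs the `centered_stack` the components were fitted to.
#' @return a tibble with one row per retained component: `component`,
#'   `variance` (raw score variance `sum(s^2)/N`), `adjusted_variance`,
#'   `cumulative_adjusted`, plus `total_variance` as an attribute.
#' @export
adjusted_explained_variance <- function(components, cs) {
  stopifnot(length(components) >= 1)
  N <- n_subjects(cs)
  Bcols <- vapply(components, function(co) vec(co$B),
                  numeric(cs$D^2))
  S <- t(vapply(components, function(co) co$scores, numeric(N)))  # m x N
  m <- ncol(Bcols)
  Btilde <- matrix(0, nrow(Bcols), 0)
  keep <- integer()
  for (j in seq_len(m)) {
    b <- Bcols[, j]
    if (ncol(Btilde) > 0) b <- b - Btilde %*% crossprod(Btilde, b)
    nb <- sqrt(sum(b^2))
    if (nb < 1e-10) {
      warning(sprintf("component %d linearly dependent on predecessors; dropped from the adjusted basis", j),
              call. = FALSE)
      next
    }
    Btilde <- cbind(Btilde, b / nb)
    keep <- c(keep, j)
  }
  # adjusted scores: coordinates of sum_m s_mn B_m in the orthonormal basis
  Stilde <- crossprod(Btilde, Bcols %*% S)
  adj <- rowSums(Stilde^2) / N
  raw <- rowSums(S[keep, , drop = FALSE]^2) / N
  out <- tibble::tibble(component = keep, variance = raw,
                        adjusted_variance = adj,
                        cumulative_adjusted = cumsum(adj))
  attr(out, "total_variance") <- total_variance(cs)
  out
}

#' @export
print.mcf_component <- function(x, ...) {
  cat(sprintf("<mcf_component> K = %d modules, objective %.6g, %s after %d iterations\n",
              x$K, x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  sizes <- colSums(x$W > 0)
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mcf_model <- function(x, ...) {
  cat(sprintf("<mcf_model> %d component(s), K = %d modules each\n",
              x$M, x$K))
  cat(sprintf("  adjusted explained variance: %.4g of total %.4g\n",
              max(x$adjusted$cumulative_adjusted), x$total_variance))
  invisible(x)
}
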