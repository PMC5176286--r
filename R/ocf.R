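#' Fit one orthogonal connectivity factorization component
#'
#' The baseline rank-two decomposition: maximize
#' `sum_n (w1' X~_n w2)^2` over orthonormal weight vectors `w1, w2`. The
#' eigenconnectivity matrix is `B = (w1 w2' + w2 w1') / sqrt(2)` (unit
#' Frobenius norm), which models inter-module variability only — the
#' intra-module terms `w1 w1'` and `w2 w2'` are absent by construction.
#'
#' The solver alternates an auxiliary unit vector `r` proportional to the
#' current scores with a closed-form inner update: with
#' `C = sum_n r_n X~_n`, the maximum of `w1' C w2` over orthonormal pairs is
#' `(lambda_max - lambda_min)/2`, attained at
#' `w1 = (u_max + u_min)/sqrt(2)`, `w2 = (u_max - u_min)/sqrt(2)` where
#' `u_max, u_min` are the eigenvectors of C's extreme eigenvalues. The first
#' restart is initialized from the rank-two eigenvectors of the leading PCA
#' eigenconnectivity; further restarts use random orthonormal pairs.
#'
#' @param cs a `centered_stack`.
#' @param config a [solver_config()]; `n_restarts` controls the multi-start.
#' @return an object of class `ocf_component`: `w1`, `w2`, `B`, `scores`
#'   (`tr[B' X~_n]`), `objective` (`sum_n (w1' X~_n w2)^2`),
#'   `objective_trace`, `converged`, `iterations`.
#' @export
ocf_fit_component <- function(cs, config = solver_config()) {
  stopifnot(inherits(cs, "centered_stack"))
  D <- cs$D
  if (sum(cs$data^2) == 0) stop("degenerate stack: no variability",
                                call. = FALSE)
  e_pca <- eigen(pca_first_component(cs)$B, symmetric = TRUE)
  pca_pair <- extreme_pair(e_pca)
  seeds <- derive_seeds(config$seed, config$n_restarts)
  best <- NULL
  for (rep in seq_len(config$n_restarts)) {
    init <- if (rep == 1) pca_pair else random_orthonormal_pair(D, seeds[[rep]])
    fit <- ocf_alternate(cs, init$w1, init$w2, config)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best
}

random_orthonormal_pair <- function(D, seed = NULL) {
  with_seed(seed, {
    A <- qr.Q(qr(matrix(stats::rnorm(D * 2), D, 2)))
    list(w1 = A[, 1], w2 = A[, 2])
  })
}

# (w1, w2) maximizing w1' C w2 for a symmetric eigendecomposition e of C.
extreme_pair <- function(e) {
  u_max <- e$vectors[, 1]
  u_min <- e$vectors[, ncol(e$vectors)]
  list(w1 = (u_max + u_min) / sqrt(2), w2 = (u_max - u_min) / sqrt(2))
}

ocf_alternate <- function(cs, w1, w2, config) {
  h <- stack_half(cs)
  D <- cs$D
  # w1' X~_n w2 = <X~_n, (w1 w2' + w2 w1')/2> for symmetric X~_n
  obj_of <- function(w1, w2) {
    half_scores(h, (tcrossprod(w1, w2) + tcrossprod(w2, w1)) / 2)
  }
  s <- obj_of(w1, w2)
  trace <- sum(s^2)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_outer_iters) {
    iter <- iter + 1L
    ns <- sqrt(sum(s^2))
    if (ns == 0) break
    r <- s / ns
    C <- half_weighted_sum(h, r)
    pair <- extreme_pair(eigen(C, symmetric = TRUE))
    w1 <- pair$w1
    w2 <- pair$w2
    s <- obj_of(w1, w2)
    obj <- sum(s^2)
    done <- abs(obj - trace[length(trace)]) <=
      config$eps_main * max(1, abs(obj))
    trace <- c(trace, obj)
    if (done) {
      converged <- TRUE
      break
    }
  }
  B <- (tcrossprod(w1, w2) + tcrossprod(w2, w1)) / sqrt(2)
  sgn <- largest_entry_sign(B)
  if (sgn < 0) {
    w1 <- -w1
    B <- -B
  }
  structure(
    list(w1 = w1, w2 = w2, B = B,
         scores = half_scores(h, B),
         objective = trace[length(trace)], objective_trace = trace,
         converged = converged, iterations = iter,
         node_labels = cs$node_labels, subject_ids = cs$subject_ids),
    class = "ocf_component")
}

#' Fit several OCF components by deflation
#'
#' As [ocf_fit_component()], deflating `s_n * B` from the centered matrices
#' between components.
#'
#' @param cs a `centered_stack`.
#' @param M number of components.
#' @param config a [solver_config()].
#' @return list of `ocf_component` objects.
#' @export
ocf_fit <- function(cs, M = 1L, config = solver_config()) {
  residual <- cs
  seeds <- derive_seeds(config$seed, M)
  out <- vector("list", M)
  for (m in seq_len(M)) {
    cfg <- config
    cfg$seed <- seeds[[m]]
    fit <- ocf_fit_component(residual, cfg)
    out[[m]] <- fit
    residual$data <- residual$data - fit$scores %*% t(vec(fit$B))
  }
  out
}

#' @export
print.ocf_component <- function(x, ...) {
  cat(sprintf("<ocf_component> objective %.6g, %s after %d iterations\n",
              x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
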