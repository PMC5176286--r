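#' Random rotation initializer with nonnegativity-oriented sign fix
#'
#' Draws a random K x K orthogonal matrix and flips the signs of its rows so
#' that every entry of `V %*% u_bar` is nonnegative, which biases the
#' rotated eigenvectors `U %*% t(V)` toward nonnegative column sums before
#' the projection onto the disjoint nonnegative set. `sign(0)` is treated as
#' +1.
#'
#' @param u_bar length-K vector of eigenvector column sums (`t(U) %*% 1`).
#' @param seed optional integer seed.
#' @param V optional K x K orthogonal matrix; when supplied, only the sign
#'   fix is applied to it instead of drawing a random rotation.
#' @return a K x K orthogonal matrix `V` with `all(V %*% u_bar >= 0)`.
#' @export
init_rotation <- function(u_bar, seed = NULL, V = NULL) {
  K <- length(u_bar)
  if (is.null(V)) V <- with_seed(seed, random_orthogonal(K))
  stopifnot(all(dim(V) == K))
  diag(sign_pos(drop(V %*% u_bar)), K) %*% V
}

#' Stepwise modular factorization of a symmetric matrix
#'
#' Factorizes a symmetric matrix B (typically a PCA eigenconnectivity
#' matrix, but any symmetric matrix is accepted) as `B ~ W G W'` where W has
#' disjoint nonnegative unit-norm columns and `G = W' B W`. The rank-K
#' eigenvector basis U of B is rotated by an orthogonal V and projected onto
#' the feasible set, alternating a projection step `W <- P(U t(V))` with an
#' orthogonal Procrustes update `V <- R t(L)` from the SVD `U'W = L S R'`,
#' until V stabilizes. A rotation that projects to a zero column is
#' re-randomized (at most `max_restarts` times).
#'
#' @param B symmetric D x D matrix.
#' @param K number of modules, `K < D`.
#' @param config a [solver_config()]; uses `eps_stepwise` and `seed`.
#' @param max_restarts cap on re-randomizations of V.
#' @return list with `W` (D x K, disjoint nonnegative orthonormal columns),
#'   `G` (K x K, `t(W) %*% B %*% W`), `iterations`, `restarts`.
#' @export
stepwise_factorize <- function(B, K, config = solver_config(),
                               max_restarts = 100L) {
  B <- as.matrix(B)
  if (!is_symmetric_tol(B, 1e-8)) stop("B must be symmetric", call. = FALSE)
  lr <- low_rank_eigen(B, K)
  U <- lr$U
  u_bar <- colSums(U)
  seeds <- derive_seeds(config$seed, max_restarts + 1L)
  V <- init_rotation(u_bar, seeds[[1]])
  restarts <- 0L
  iter <- 0L
  max_iter <- 1000L
  repeat {
    iter <- iter + 1L
    V_old <- V
    W <- project_omega_plus(U %*% t(V))
    if (any(colSums(W^2) == 0)) {
      restarts <- restarts + 1L
      if (restarts > max_restarts) {
        stop(sprintf(
          "stepwise factorization failed: restart cap %d exceeded (K = %d, seed = %s)",
          max_restarts, K, format(config$seed)), call. = FALSE)
      }
      V <- init_rotation(u_bar, seeds[[restarts + 1L]])
      next
    }
    sv <- svd(crossprod(U, W))
    V <- sv$v %*% t(sv$u)
    if (frob(crossprod(V_old, V) - diag(K)) < config$eps_stepwise) break
    if (iter >= max_iter) break
  }
  W <- normalize_columns(W)
  G <- crossprod(W, B %*% W)
  list(W = W, G = (G + t(G)) / 2, iterations = iter, restarts = restarts)
}
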