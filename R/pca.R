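#' Leading PCA eigenconnectivity of a centered stack
#'
#' Finds the unit-Frobenius-norm symmetric matrix B maximizing
#' `sum_n (tr[B' X~_n])^2`, i.e. the direction in matrix space along which
#' the centered connectivity matrices vary most. The score of matrix n is
#' `s_n = tr[B' X~_n]`. Computed as the top eigenvector of the vectorized
#' second-moment matrix; when `D^2 > N` the equivalent N x N Gram route is
#' used. The global sign is fixed so the largest-magnitude entry of B is
#' positive.
#'
#' @param cs a `centered_stack`.
#' @return an object of class `eigenconnectivity`: list with `B` (D x D
#'   symmetric, unit norm), `scores` (length-N), `explained_variance`
#'   (sample variance along B, `sum(scores^2)/N`).
#' @export
pca_first_component <- function(cs) {
  comps <- pca_components(cs, 1)
  comps[[1]]
}

#' Multiple PCA eigenconnectivities by deflation
#'
#' Extracts `M` components one by one; after each, the explained part
#' `s_n * B` is subtracted from every centered matrix so the next component
#' maximizes the residual variance. Components are mutually orthogonal and
#' ordered by nonincreasing explained variance. If `M` exceeds the rank of
#' the variability, the list is truncated with a warning.
#'
#' @param cs a `centered_stack`.
#' @param M number of components, `M >= 1`.
#' @return list of `eigenconnectivity` objects.
#' @export
pca_components <- function(cs, M) {
  stopifnot(inherits(cs, "centered_stack"), M >= 1)
  Xmat <- cs$data
  D <- cs$D
  tv0 <- sum(Xmat^2)
  if (tv0 <= 0) stop("degenerate stack: no variability", call. = FALSE)
  tops <- top_vec_eigen(Xmat, D, M)
  out <- list()
  for (m in seq_along(tops$values)) {
    if (tops$values[m] <= max(1e-12 * tv0, 0)) {
      warning(sprintf("variability exhausted after %d component(s); %d requested",
                      m - 1L, M), call. = FALSE)
      break
    }
    B <- tops$B[[m]] * largest_entry_sign(tops$B[[m]])
    s <- drop(Xmat %*% vec(B))
    out[[m]] <- structure(
      list(B = B, scores = s, explained_variance = sum(s^2) / nrow(Xmat),
           node_labels = cs$node_labels, subject_ids = cs$subject_ids),
      class = "eigenconnectivity")
  }
  out
}

# Leading M eigenpairs of sum_n vec(X~_n) vec(X~_n)': direct D^2 x D^2
# route for small D, N x N Gram route otherwise (identical spectra; both
# are exercised in the tests). Because the basis matrices of successive
# components are mutually orthogonal, extracting M leading eigenpairs at
# once coincides with recursive rank-one deflation; the equivalence is
# asserted in the test suite.
top_vec_eigen <- function(Xmat, D, M = 1L) {
  N <- nrow(Xmat)
  if (D * D <= N) {
    S <- crossprod(Xmat)              # D^2 x D^2
    e <- eigen(S, symmetric = TRUE)
    M <- min(M, ncol(e$vectors))
    bs <- lapply(seq_len(M), function(m) e$vectors[, m])
    vals <- e$values[seq_len(M)]
  } else {
    Gm <- tcrossprod(Xmat)            # N x N Gram matrix
    e <- eigen(Gm, symmetric = TRUE)
    M <- min(M, ncol(e$vectors))
    vals <- e$values[seq_len(M)]
    bs <- lapply(seq_len(M), function(m) {
      b <- drop(crossprod(Xmat, e$vectors[, m]))
      nb <- sqrt(sum(b^2))
      if (nb > 0) b / nb else b
    })
  }
  Bs <- lapply(bs, function(b) {
    B <- unvec(b, D)
    B <- (B + t(B)) / 2               # symmetric data keeps B symmetric;
    nb <- frob(B)                     # guard against rounding drift
    if (nb > 0) B / nb else B
  })
  list(B = Bs, values = vals)
}

#' Eigenvalue spectrum of an eigenconnectivity matrix
#'
#' Orthogonally decomposes the squared Frobenius norm of a symmetric matrix
#' B into squared eigenvalues. The cumulative proportions of the squared
#' eigenvalues indicate how many modules K are needed for a rank-K
#' factorization of B to retain most of its power; `order = "magnitude"`
#' ranks eigenvalues by absolute value (the order used by the rank-K
#' truncation), `order = "value"` sorts by signed value.
#'
#' @param B an `eigenconnectivity` object or a symmetric D x D matrix.
#' @param order `"value"` (default) or `"magnitude"`.
#' @return a tibble with columns `index`, `eigenvalue`,
#'   `squared_proportion`, `squared_cumulative`; the cumulative column is
#'   nondecreasing and ends at 1.
#' @export
eigen_spectrum <- function(B, order = c("value", "magnitude")) {
  order <- match.arg(order)
  if (inherits(B, "eigenconnectivity")) B <- B$B
  B <- as.matrix(B)
  if (!is_symmetric_tol(B, 1e-8)) stop("B must be symmetric", call. = FALSE)
  q <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (order == "magnitude") q <- q[order(abs(q), decreasing = TRUE)]
  p <- q^2 / sum(q^2)
  out <- tibble::tibble(index = seq_along(q), eigenvalue = q,
                        squared_proportion = p,
                        squared_cumulative = cumsum(p))
  class(out) <- c("mcf_spectrum", class(out))
  out
}

#' Best rank-K symmetric approximation by eigen-truncation
#'
#' Keeps the K eigenpairs of largest absolute eigenvalue; `U %*% diag(Q) %*%
#' t(U)` is then the Frobenius-nearest rank-K symmetric matrix
#' (Eckart-Young).
#'
#' @param B symmetric D x D matrix.
#' @param K target rank, `K < D`.
#' @return list with `U` (D x K eigenvectors) and `Q` (length-K signed
#'   eigenvalues).
#' @export
low_rank_eigen <- function(B, K) {
  B <- as.matrix(B)
  D <- nrow(B)
  if (K >= D) stop("K must be smaller than the matrix dimension",
                   call. = FALSE)
  if (!is_symmetric_tol(B, 1e-8)) stop("B must be symmetric", call. = FALSE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- order(abs(e$values), decreasing = TRUE)[seq_len(K)]
  keep <- sort(keep)  # preserve the nonincreasing-value order among kept pairs
  list(U = e$vectors[, keep, drop = FALSE], Q = e$values[keep])
}

#' @export
print.eigenconnectivity <- function(x, ...) {
  cat(sprintf("<eigenconnectivity> %d x %d, explained variance %.4g\n",
              nrow(x$B), ncol(x$B), x$explained_variance))
  invisible(x)
}
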