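#' Project a matrix onto the disjoint nonnegative weight set
#'
#' The feasible set for module weight matrices contains every D x K matrix
#' that is entrywise nonnegative with at most one nonzero entry per row, so
#' that modules are disjoint node sets. The constraint decouples across rows,
#' which gives a closed-form Frobenius-nearest projection: in each row, keep
#' the largest strictly positive entry and zero the rest; rows with no
#' positive entry become all-zero. Ties between equal row maxima are broken
#' by the lowest column index, so the projection is deterministic.
#'
#' @param A a finite D x K numeric matrix.
#' @return the projected D x K matrix.
#' @export
project_omega_plus <- function(A) {
  A <- as.matrix(A)
  stopifnot_finite(A, "projection input")
  out <- matrix(0, nrow(A), ncol(A))
  j <- max.col(A, ties.method = "first")
  v <- A[cbind(seq_len(nrow(A)), j)]
  keep <- v > 0
  out[cbind(which(keep), j[keep])] <- v[keep]
  dimnames(out) <- dimnames(A)
  out
}

#' Scale every column of a matrix to unit Euclidean norm
#'
#' Used after the projection so each module weight vector has unit norm.
#' For a matrix in the disjoint nonnegative set this yields orthonormal
#' columns (disjoint supports imply orthogonality).
#'
#' @param W a D x K matrix whose columns all have norm above `tol`.
#' @param tol norm below which a column is reported as degenerate.
#' @return `W` with unit-norm columns.
#' @export
normalize_columns <- function(W, tol = 1e-12) {
  W <- as.matrix(W)
  nrm <- sqrt(colSums(W^2))
  if (any(nrm <= tol)) {
    stop(sprintf("degenerate module: column(s) %s have (near-)zero norm",
                 paste(which(nrm <= tol), collapse = ", ")), call. = FALSE)
  }
  sweep(W, 2, nrm, "/")
}

# TRUE when W is in the disjoint nonnegative set within tolerance.
in_omega_plus <- function(W, tol = 0) {
  all(W >= -tol) && all(rowSums(W > tol) <= 1)
}
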