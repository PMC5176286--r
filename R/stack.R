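#' Build a connectivity stack from matrices
#'
#' A connectivity stack holds N symmetric D x D connectivity matrices
#' (one per subject or time window) sharing a common node set. Internally
#' matrices are stored vectorized as the rows of an N x D^2 matrix, which is
#' the layout every solver in the package works on.
#'
#' @param matrices a list of D x D numeric matrices, or a 3-D array with
#'   dimensions D x D x N.
#' @param node_labels optional character vector of D node labels.
#' @param subject_ids optional character vector of N subject identifiers.
#' @param symmetrize one of `"average"` (replace each matrix by
#'   `(X + t(X))/2`, warning when the asymmetry exceeds `tol`) or `"strict"`
#'   (error when any matrix is asymmetric beyond `tol`).
#' @param tol symmetry tolerance, default `1e-8`.
#'
#' @return an object of class `connectivity_stack` with elements `data`
#'   (N x D^2 matrix of vectorized connectivity matrices), `D`,
#'   `node_labels`, `subject_ids`.
#' @export
as_connectivity_stack <- function(matrices, node_labels = NULL,
                                  subject_ids = NULL,
                                  symmetrize = c("average", "strict"),
                                  tol = 1e-8) {
  symmetrize <- match.arg(symmetrize)
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]), function(n) matrices[, , n])
  }
  if (!is.list(matrices) || length(matrices) < 2) {
    stop("need a list or array of at least 2 connectivity matrices",
         call. = FALSE)
  }
  N <- length(matrices)
  dims <- vapply(matrices, function(X) dim(as.matrix(X)), integer(2))
  if (any(dims[1, ] != dims[2, ])) stop("non-square matrix in stack",
                                        call. = FALSE)
  if (length(unique(dims[1, ])) != 1) {
    stop("matrices differ in dimension: ",
         paste(sort(unique(dims[1, ])), collapse = ", "), call. = FALSE)
  }
  D <- dims[1, 1]
  data <- matrix(NA_real_, N, D * D)
  max_asym <- 0
  for (n in seq_len(N)) {
    X <- as.matrix(matrices[[n]])
    stopifnot_finite(X, sprintf("matrix %d", n))
    a <- max(abs(X - t(X)))
    max_asym <- max(max_asym, a)
    if (a > tol) {
      if (symmetrize == "strict") {
        stop(sprintf("matrix %d asymmetric beyond tolerance (max |X - X'| = %g)",
                     n, a), call. = FALSE)
      }
      X <- (X + t(X)) / 2
    }
    data[n, ] <- vec(X)
  }
  if (symmetrize == "average" && max_asym > tol) {
    warning(sprintf("symmetrized %s by averaging (max asymmetry %g)",
                    "input matrices", max_asym), call. = FALSE)
  }
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(D))
  if (is.null(subject_ids)) subject_ids <- paste0("subject", seq_len(N))
  stopifnot(length(node_labels) == D, length(subject_ids) == N)
  structure(
    list(data = data, D = D,
         node_labels = as.character(node_labels),
         subject_ids = as.character(subject_ids)),
    class = "connectivity_stack"
  )
}

#' Number of matrices and nodes in a stack
#' @param stack a `connectivity_stack`.
#' @return integer count.
#' @export
n_subjects <- function(stack) nrow(stack$data)

#' @rdname n_subjects
#' @export
n_nodes <- function(stack) stack$D

#' Extract one connectivity matrix from a stack
#' @param stack a `connectivity_stack`.
#' @param n index of the matrix.
#' @return a D x D matrix with node labels as dimnames.
#' @export
stack_matrix <- function(stack, n) {
  X <- unvec(stack$data[n, ], stack$D)
  dimnames(X) <- list(stack$node_labels, stack$node_labels)
  X
}

#' Center a connectivity stack
#'
#' Subtracts the elementwise sample mean matrix from every connectivity
#' matrix, yielding the centered matrices that all decompositions operate on.
#'
#' @param stack a `connectivity_stack` with at least 2 matrices.
#' @return an object of class `centered_stack` (inherits
#'   `connectivity_stack`): the `data` rows are the vectorized centered
#'   matrices, `mean` is the D x D sample mean.
#' @export
center_stack <- function(stack) {
  if (!inherits(stack, "connectivity_stack")) {
    stop("expected a connectivity_stack", call. = FALSE)
  }
  if (n_subjects(stack) < 2) stop("need at least 2 matrices to center",
                                  call. = FALSE)
  mu <- colMeans(stack$data)
  centered <- sweep(stack$data, 2, mu)
  out <- stack
  out$data <- centered
  out$mean <- unvec(mu, stack$D)
  dimnames(out$mean) <- list(stack$node_labels, stack$node_labels)
  class(out) <- c("centered_stack", "connectivity_stack")
  out
}

# Total variance of a centered stack: sum_n ||X~_n||^2 / N.
total_variance <- function(cs) sum(cs$data^2) / nrow(cs$data)

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("<%s> %d matrices, %d x %d nodes\n",
              if (inherits(x, "centered_stack")) "centered_stack"
              else "connectivity_stack",
              n_subjects(x), x$D, x$D))
  invisible(x)
}
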