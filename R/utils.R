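# Small internal helpers shared across the solvers.

# Column-major vectorization and its inverse.
vec <- function(X) as.numeric(X)

unvec <- function(x, D) matrix(x, nrow = D, ncol = D)

frob <- function(X) sqrt(sum(X^2))

is_symmetric_tol <- function(X, tol = 1e-8) {
  max(abs(X - t(X))) <= tol
}

stopifnot_finite <- function(X, what = "input") {
  if (!all(is.finite(X))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(X)
}

# Haar-distributed random orthogonal K x K matrix (QR of a Gaussian matrix
# with the sign convention that makes the decomposition unique).
random_orthogonal <- function(K) {
  A <- matrix(stats::rnorm(K * K), K, K)
  qrA <- qr(A)
  Q <- qr.Q(qrA)
  d <- sign(diag(qr.R(qrA)))
  d[d == 0] <- 1
  Q %*% diag(d, K)
}

# sign() with sign(0) treated as +1, used by the rotation sign fix.
sign_pos <- function(x) {
  s <- sign(x)
  s[s == 0] <- 1
  s
}

# Fix the global sign of a matrix so its largest-magnitude entry is positive;
# ties resolved by the first (column-major) index, so the result is
# deterministic. Returns the sign applied.
largest_entry_sign <- function(B) {
  i <- which.max(abs(B))
  s <- sign_pos(B[i])
  s
}

# Derive a stream of child seeds from one user-facing seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

# Compact symmetric representation used inside the solver loops: keep only
# the upper triangle (incl. diagonal) of each vectorized matrix. Dot
# products against a symmetric matrix M are then x_half' (w * M_half) with
# off-diagonal weight 2, at half the cost of the full D^2 product.
stack_half <- function(cs) {
  D <- cs$D
  M <- matrix(seq_len(D * D), D)
  upper <- which(upper.tri(M, diag = TRUE))
  mirror <- t(M)[upper]
  w <- rep(2, length(upper))
  w[upper == mirror] <- 1
  list(Xh = cs$data[, upper, drop = FALSE], w = w,
       upper = upper, mirror = mirror, D = D)
}

half_scores <- function(h, M) {
  drop(h$Xh %*% (h$w * M[h$upper]))
}

# sum_n r_n X~_n reconstructed as a full symmetric D x D matrix.
half_weighted_sum <- function(h, r) {
  ch <- drop(crossprod(h$Xh, r))
  C <- matrix(0, h$D, h$D)
  C[h$upper] <- ch
  C[h$mirror] <- ch
  C
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
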