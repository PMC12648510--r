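#' Vectorize a matrix column by column
#'
#' Stacks the columns of a matrix into a single column vector, the standard
#' `vec` operator of matrix calculus.
#'
#' @param M A numeric matrix (a numeric vector is treated as a one-column
#'   matrix).
#' @return A numeric vector of length `nrow(M) * ncol(M)`.
#' @examples
#' vec(matrix(1:4, 2, 2))
#' @export
vec <- function(M) {
  M <- as.matrix(M)
  dim(M) <- NULL
  M
}

#' Half-vectorize a lower-triangular matrix
#'
#' Stacks the lower-triangle entries of a square matrix column by column,
#' skipping the structurally zero upper triangle, into a vector of length
#' d(d+1)/2. `lvec_inverse()` rebuilds the lower-triangular matrix exactly.
#'
#' @param L A square numeric matrix; only its lower triangle is read.
#' @return Numeric vector of length `d*(d+1)/2` where `d = nrow(L)`.
#' @seealso [lvec_inverse()], [lvec_index()]
#' @export
lvec <- function(L) {
  L <- as.matrix(L)
  d <- nrow(L)
  if (ncol(L) != d) stop("lvec() requires a square matrix", call. = FALSE)
  L[lower.tri(L, diag = TRUE)]
}

#' @rdname lvec
#' @param v Numeric vector of length `d*(d+1)/2` for some positive integer d.
#' @export
lvec_inverse <- function(v) {
  n <- length(v)
  d <- (sqrt(8 * n + 1) - 1) / 2
  if (abs(d - round(d)) > 1e-8) {
    stop("length of `v` is not a triangular number d*(d+1)/2", call. = FALSE)
  }
  d <- as.integer(round(d))
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

#' Position of a lower-triangle entry in the half-vectorization
#'
#' Maps the matrix index (i, j) with j <= i to its 1-based position in the
#' column-major lower-triangle stacking of a d1 x d1 matrix:
#' `(2*d1 - j + 2)*(j - 1)/2 + i - j + 1`.
#'
#' @param i,j Row and column index, `1 <= j <= i <= d1`.
#' @param d1 Matrix dimension.
#' @return Integer position in `1:(d1*(d1+1)/2)`.
#' @export
lvec_index <- function(i, j, d1) {
  if (any(j > i)) stop("lvec_index() is defined only for j <= i (lower triangle)",
                       call. = FALSE)
  if (any(i > d1) || any(j < 1)) stop("index out of range", call. = FALSE)
  as.integer((2 * d1 - j + 2) * (j - 1) / 2 + i - j + 1)
}

#' Commutation matrix
#'
#' The mn x mn permutation matrix K with `K %*% vec(A) == vec(t(A))` for
#' every m x n matrix A. Materialized densely; intended for small m, n.
#'
#' @param m,n Positive integers.
#' @return An `m*n` x `m*n` 0/1 permutation matrix.
#' @export
commutation_matrix <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  mn <- m * n
  # vec(t(A))[p] = vec(A)[q]: entry (i,j) sits at (j-1)*m+i in vec(A) and at
  # (i-1)*n+j in vec(t(A))
  K <- matrix(0, mn, mn)
  i <- rep(seq_len(m), times = n)
  j <- rep(seq_len(n), each = m)
  K[cbind((i - 1) * n + j, (j - 1) * m + i)] <- 1
  K
}

#' Symmetrize and regularize a matrix until it is positive definite
#'
#' Replaces M by (M + t(M))/2 and, if a Cholesky factorization still fails,
#' adds jitter `c * I` with `c` escalating by factors of 10 from
#' `jitter_scale` until the factorization succeeds. The amount of jitter
#' applied is returned so callers can audit regularization events; jitter
#' beyond `1e6 * jitter_scale` is treated as a diverged state.
#'
#' @param M Square numeric matrix with finite entries.
#' @param jitter_scale Starting jitter magnitude (default `1e-10`).
#' @return The regularized symmetric positive-definite matrix, with
#'   attribute `"jitter"` (0 when none was needed).
#' @export
ensure_spd <- function(M, jitter_scale = 1e-10) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("ensure_spd() requires a square matrix", call. = FALSE)
  if (!all(is.finite(M))) {
    stop("ensure_spd(): non-finite entries (diverged filter state)", call. = FALSE)
  }
  S <- (M + t(M)) / 2
  jitter <- 0
  step <- jitter_scale
  d <- nrow(S)
  repeat {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) break
    if (step > 1e6 * jitter_scale) {
      stop("ensure_spd(): jitter escalation exceeded 1e6 * jitter_scale ",
           "(diverged filter state)", call. = FALSE)
    }
    S <- S + diag(step, d)
    jitter <- jitter + step
    step <- step * 10
  }
  attr(S, "jitter") <- jitter
  S
}

# Cholesky-based SPD inverse; A is assumed symmetric (guard upstream).
chol_inv <- function(A) {
  chol2inv(chol(A))
}

# closed-form inverse of a symmetric positive-definite 2x2 or 3x3 matrix;
# NULL when a leading principal minor is non-positive (not PD)
sym_inv_small <- function(S) {
  n <- nrow(S)
  if (n == 2L) {
    a <- S[1L]; b <- S[2L]; d <- S[4L]
    det <- a * d - b * b
    if (a <= 0 || det <= 0 || !is.finite(det)) return(NULL)
    matrix(c(d, -b, -b, a), 2L, 2L) / det
  } else {
    a <- S[1L]; b <- S[2L]; c <- S[3L]; d <- S[5L]; e <- S[6L]; f <- S[9L]
    m2 <- a * d - b * b
    det <- a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d)
    if (a <= 0 || m2 <= 0 || det <= 0 || !is.finite(det)) return(NULL)
    matrix(c(d * f - e * e, c * e - b * f, b * e - c * d,
             c * e - b * f, a * f - c * c, b * c - a * e,
             b * e - c * d, b * c - a * e, m2), 3L, 3L) / det
  }
}

# Invert with the ensure_spd escalation policy; returns inverse, jitter attr.
# Fast paths: closed-form inverse for d <= 3, one Cholesky otherwise;
# escalate only on failure.
guarded_inv <- function(A, jitter_scale = 1e-10) {
  S <- (A + t(A)) / 2
  n <- nrow(S)
  if (n <= 3L) {
    Inv <- if (n == 1L) {
      if (is.finite(S[1L]) && S[1L] > 0) matrix(1 / S[1L], 1L, 1L) else NULL
    } else sym_inv_small(S)
    if (!is.null(Inv)) {
      attr(Inv, "jitter") <- 0
      return(Inv)
    }
  } else {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(R)) {
      Inv <- chol2inv(R)
      attr(Inv, "jitter") <- 0
      return(Inv)
    }
  }
  S <- ensure_spd(S, jitter_scale)
  Inv <- chol2inv(chol(S))
  attr(Inv, "jitter") <- attr(S, "jitter")
  Inv
}

# dense Kronecker product for small matrices (faster than kronecker())
kron_ <- function(A, B) {
  p <- nrow(A); q <- ncol(A); r <- nrow(B); s <- ncol(B)
  A[rep(seq_len(p), each = r), rep(seq_len(q), each = s), drop = FALSE] *
    B[rep.int(seq_len(r), p), rep.int(seq_len(s), q), drop = FALSE]
}
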