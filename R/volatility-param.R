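#' Second-level volatility coupling
#'
#' Parameters of the affine map from the second-level state x2 to the
#' log-space volatility vector y2 = W2 x2 + b2, where W2 = diag(w2) with
#' strictly positive coupling strengths and b2 is a bias. y2 has length
#' d2 = d1(d1+1)/2: one component per lower-triangle entry of the Cholesky
#' factor of the level-1 diffusion matrix.
#'
#' @param w2 Positive numeric vector of length `d1*(d1+1)/2`.
#' @param b2 Numeric vector of the same length (default all 0).
#' @param d1 Signal dimension.
#' @return An object of class `"volatility_coupling"`.
#' @export
volatility_coupling <- function(w2, b2 = rep(0, length(w2)), d1) {
  d2 <- d1 * (d1 + 1) / 2
  if (length(w2) != d2 || length(b2) != d2) {
    stop("w2 and b2 must have length d1*(d1+1)/2 = ", d2, call. = FALSE)
  }
  if (any(w2 <= 0)) stop("all coupling strengths w2 must be > 0", call. = FALSE)
  structure(list(w2 = as.numeric(w2), b2 = as.numeric(b2),
                 d1 = as.integer(d1), d2 = as.integer(d2)),
            class = "volatility_coupling")
}

#' Log-space volatility vector from the second-level state
#'
#' @param x2 Numeric vector of length d2.
#' @param coupling A [volatility_coupling()].
#' @return y2 = w2 * x2 + b2 (elementwise).
#' @export
y2_from_x2 <- function(x2, coupling) {
  if (length(x2) != coupling$d2) stop("x2 has wrong length", call. = FALSE)
  coupling$w2 * x2 + coupling$b2
}

# Bound on |y2| before exp/sinh/cosh; exp(30) ~ 1e13 already marks divergence.
Y2_CLAMP <- 30

clamp_y2 <- function(y2, clamp = Y2_CLAMP) {
  over <- abs(y2) > clamp
  if (!any(over)) {
    attr(y2, "n_clamped") <- 0L
    return(y2)
  }
  y <- pmin(pmax(y2, -clamp), clamp)
  attr(y, "n_clamped") <- sum(over)
  y
}

#' Cholesky volatility factor from its log-space parameterization
#'
#' Builds the lower-triangular factor L1 of the level-1 diffusion matrix
#' from the d1(d1+1)/2 log-space parameters y2: diagonal entries are
#' `exp(y2)` (strictly positive), off-diagonal entries are `2*sinh(y2)`
#' (any sign), placed in column-major lower-triangle order. The diffusion
#' matrix Sigma1 = L1 L1' is then symmetric positive definite for any
#' finite y2.
#'
#' Components of y2 are clamped to `[-30, 30]` before the transcendental
#' maps; the number of clamped components is attached as attribute
#' `"n_clamped"`.
#'
#' @param y2 Numeric vector of length `d1*(d1+1)/2`.
#' @param d1 Signal dimension.
#' @return Lower-triangular d1 x d1 matrix.
#' @seealso [y2_from_L1()] for the exact inverse.
#' @export
L1_from_y2 <- function(y2, d1) {
  d2 <- d1 * (d1 + 1) / 2
  if (length(y2) != d2) stop("y2 must have length d1*(d1+1)/2", call. = FALSE)
  cst <- d1_constants(d1)
  y2 <- clamp_y2(y2)
  v <- 2 * sinh(y2)
  v[cst$isdiag] <- exp(y2[cst$isdiag])
  L <- matrix(0, d1, d1)
  L[cst$lower_idx] <- v
  attr(L, "n_clamped") <- attr(y2, "n_clamped")
  L
}

#' @rdname L1_from_y2
#' @param L1 Lower-triangular matrix with strictly positive diagonal.
#' @export
y2_from_L1 <- function(L1) {
  L1 <- as.matrix(L1)
  d1 <- nrow(L1)
  if (any(diag(L1) <= 0)) {
    stop("y2_from_L1(): diagonal of L1 must be strictly positive", call. = FALSE)
  }
  v <- lvec(L1)
  y2 <- asinh(v / 2)
  diag_pos <- lvec_index(seq_len(d1), seq_len(d1), d1)
  y2[diag_pos] <- log(v[diag_pos])
  y2
}

# TRUE at lvec positions holding a diagonal entry of a d1 x d1 lower triangle.
lvec_is_diag <- function(d1) {
  out <- logical(d1 * (d1 + 1) / 2)
  out[lvec_index(seq_len(d1), seq_len(d1), d1)] <- TRUE
  out
}

# vec(L1) position of lvec position m: (i,j) -> (j-1)*d1 + i.
lvec_to_vec_pos <- function(d1) {
  pos <- integer(d1 * (d1 + 1) / 2)
  for (j in seq_len(d1)) {
    for (i in j:d1) {
      pos[lvec_index(i, j, d1)] <- (j - 1) * d1 + i
    }
  }
  pos
}

#' Jacobian of the volatility factor with respect to its log-space parameters
#'
#' Row m of the returned d2 x d1^2 matrix is `f'(y2[m]) * e2(m)'`, where
#' `f'` is `exp` at lvec positions holding a diagonal entry of L1 and
#' `2*cosh` at off-diagonal positions (the derivative of the two branches of
#' the Cholesky parameterization), y2 is evaluated at the previous
#' second-level mean, and `e2(m)` indicates where lvec position m sits
#' inside `vec(L1)`. Each row therefore has exactly one nonzero entry, and
#' `W2 %*% Lg` is the transposed Jacobian of `x2 -> vec(L1)`.
#'
#' @param mu2_prev Second-level mean at the previous trial, length d2.
#' @param coupling A [volatility_coupling()].
#' @return A d2 x d1^2 matrix.
#' @export
Lg_jacobian <- function(mu2_prev, coupling) {
  d1 <- coupling$d1
  d2 <- coupling$d2
  cst <- d1_constants(d1)
  y2 <- clamp_y2(y2_from_x2(mu2_prev, coupling))
  fprime <- 2 * cosh(y2)
  fprime[cst$isdiag] <- exp(y2[cst$isdiag])
  Lg <- matrix(0, d2, d1 * d1)
  Lg[cbind(seq_len(d2), cst$vecpos)] <- fprime
  Lg
}
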