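#' Level-1 prediction step
#'
#' From the previous-trial posteriors, forms the predicted Cholesky factor
#' `L1_hat = F2(mu2_prev)`, the predicted diffusion matrix
#' `Sigma1_hat = L1_hat L1_hat'`, the prediction precision
#' `Pi1_hat = (epsilon * Sigma1_hat + C1_prev)^-1`, and the predicted rate
#' `r_hat = exp(W1 mu1_prev + b1)`.
#'
#' @param belief1_prev,belief2_prev [gaussian_belief()]s from trial k-1.
#' @param params An [hbf_params()].
#' @param config A [filter_config()].
#' @return List with `r_hat`, `L1_hat`, `Sigma1_hat`, `S` (the prediction
#'   covariance `epsilon * Sigma1_hat + C1_prev`), `Pi1_hat`, and the
#'   diagnostic counters `jitter`, `n_clamped`.
#' @export
predict_level1 <- function(belief1_prev, belief2_prev, params, config = filter_config()) {
  y2 <- y2_from_x2(belief2_prev$mu, params$vol)
  L1_hat <- L1_from_y2(y2, params$d1)
  n_clamped <- attr(L1_hat, "n_clamped") %||% 0L
  attr(L1_hat, "n_clamped") <- NULL
  Sigma1_hat <- tcrossprod(L1_hat)
  S <- config$epsilon * Sigma1_hat + belief1_prev$C
  Pi1_hat <- guarded_inv(S, config$jitter_scale)
  jit <- attr(Pi1_hat, "jitter") %||% 0
  attr(Pi1_hat, "jitter") <- NULL
  list(r_hat = rate_from_x1(belief1_prev$mu, params$obs),
       L1_hat = L1_hat, Sigma1_hat = Sigma1_hat,
       S = S, Pi1_hat = Pi1_hat,
       jitter = jit, n_clamped = n_clamped)
}

#' Level-1 update step
#'
#' One Newton step on the level-1 variational energy, in closed form: the
#' posterior precision is `P1 = Pi1_hat + W1' diag(o * r_hat) W1`, its
#' inverse the new covariance, and the mean moves by the
#' covariance-weighted prediction error `mu1 = mu1_prev + C1 W1' PE0`.
#' The precision is updated before the mean (the mean update uses the new
#' covariance).
#'
#' @param o Non-negative observation vector.
#' @param belief1_prev Previous level-1 [gaussian_belief()].
#' @param prediction Output of [predict_level1()].
#' @inheritParams predict_level1
#' @return List with `belief` (the new level-1 belief) and `PE0`.
#' @export
update_level1 <- function(o, belief1_prev, prediction, params, config = filter_config()) {
  if (any(o < 0)) stop("observations must be non-negative", call. = FALSE)
  w1 <- params$obs$w1
  a <- o * prediction$r_hat
  P1 <- prediction$Pi1_hat + diag(w1^2 * a, params$d1)
  C1 <- guarded_inv(P1, config$jitter_scale)
  attr(C1, "jitter") <- NULL
  PE0 <- 1 - a
  mu1 <- belief1_prev$mu + drop(C1 %*% (w1 * PE0))
  list(belief = structure(list(mu = mu1, C = C1, P = P1),
                          class = "gaussian_belief"),
       PE0 = PE0)
}

#' Level-1 variational energy
#'
#' The expected log-joint as a function of the level-1 state (additive
#' constants dropped):
#' `sum(W1 x1 + b1) - o' exp(W1 x1 + b1)
#'  - (x1 - mu1_prev)' Pi1_hat (x1 - mu1_prev) / 2`.
#' Its single-step Newton maximization from `mu1_prev` is exactly
#' [update_level1()]; exposed for testing the analytic gradient and Hessian.
#'
#' @param x1 Level-1 state vector at which to evaluate.
#' @inheritParams update_level1
#' @return Scalar energy value.
#' @export
variational_energy_V1 <- function(x1, o, belief1_prev, prediction, params,
                                  config = filter_config()) {
  w1 <- params$obs$w1
  b1 <- params$obs$b1
  eta <- w1 * x1 + b1
  d <- x1 - belief1_prev$mu
  sum(eta) - sum(o * exp(eta)) - 0.5 * drop(crossprod(d, prediction$Pi1_hat %*% d))
}

#' @rdname variational_energy_V1
#' @export
grad_V1 <- function(x1, o, belief1_prev, prediction, params,
                    config = filter_config()) {
  w1 <- params$obs$w1
  rate <- exp(w1 * x1 + params$obs$b1)
  w1 * (1 - o * rate) - drop(prediction$Pi1_hat %*% (x1 - belief1_prev$mu))
}

#' @rdname variational_energy_V1
#' @export
hessian_V1 <- function(x1, o, belief1_prev, prediction, params,
                       config = filter_config()) {
  w1 <- params$obs$w1
  rate <- exp(w1 * x1 + params$obs$b1)
  -diag(w1^2 * (o * rate), params$d1) - prediction$Pi1_hat
}

#' Level-2 update step
#'
#' Propagates the level-1 belief change up to the volatility level. With
#' `PE1 = mu1 - mu1_prev`, `Delta1 = (C1 + PE1 PE1') Pi1_hat - I` and
#' `Omega1_hat = L1_hat' Pi1_hat`, the posterior precision is assembled
#' from the printed closed form (commutation-matrix term, Kronecker
#' products, and the `-W2' diag(lvec(delta1)) W2` correction), symmetrized
#' and guarded to be positive definite, and the mean then moves by
#' `epsilon * C2 W2' Lg (Omega1_hat (x) I) vec(Delta1')`. Precision before
#' mean.
#'
#' @param belief2_prev Previous level-2 [gaussian_belief()].
#' @param belief1_prev,belief1_new Level-1 beliefs before and after
#'   [update_level1()].
#' @inheritParams update_level1
#' @return List with `belief` (new level-2 belief), `intermediates`
#'   (`PE1`, `Delta1`, `Omega1_hat`, `Lg`, `delta1`, `Pi2_hat`), and the
#'   jitter applied by the positive-definiteness guard.
#' @export
update_level2 <- function(belief2_prev, belief1_prev, belief1_new, prediction,
                          params, config = filter_config()) {
  d1 <- params$d1
  eps <- config$epsilon
  w2 <- params$vol$w2
  L1 <- prediction$L1_hat
  Pi1 <- prediction$Pi1_hat

  PE1 <- belief1_new$mu - belief1_prev$mu
  M <- belief1_new$C + tcrossprod(PE1)
  Delta1 <- M %*% Pi1
  diag(Delta1) <- diag(Delta1) - 1

  Omega <- crossprod(L1, Pi1)            # L1' Pi1
  OT <- t(Omega)
  OD <- Omega %*% Delta1
  DtOt <- t(OD)                          # Delta1' Omega'
  PiD <- Pi1 %*% Delta1
  Lt <- t(L1)

  cst <- d1_constants(d1)
  iA <- cst$krA
  iB <- cst$krB
  kd <- function(A, B) A[iA, iA, drop = FALSE] * B[iB, iB, drop = FALSE]
  braces <-
    eps^2 * (cst$Kd %*% (kd(OT, OD) + kd(DtOt, Omega) + kd(OT, Omega))) +
    eps^2 * (kd(Lt %*% DtOt, Pi1) + kd(Lt %*% OT, PiD) + kd(Lt %*% OT, Pi1)) -
    eps * kd(cst$Id1, PiD)

  Lg <- Lg_jacobian(belief2_prev$mu, params$vol)
  WLg <- w2 * Lg                          # W2' Lg (W2 diagonal)
  delta1 <- eps * (DtOt * L1)             # elementwise; upper triangle zero

  Pi2_hat <- guarded_inv(eps * diag(params$lambda^2, params$d2) + belief2_prev$C,
                         config$jitter_scale)
  jit <- attr(Pi2_hat, "jitter") %||% 0
  attr(Pi2_hat, "jitter") <- NULL

  P2 <- Pi2_hat + WLg %*% braces %*% t(WLg) -
    diag(w2^2 * delta1[cst$lower_idx], params$d2)
  P2 <- ensure_spd(P2, config$jitter_scale)
  jit <- jit + attr(P2, "jitter")
  attr(P2, "jitter") <- NULL
  C2 <- chol_inv(P2)

  drive <- eps * drop(C2 %*% (w2 * (Lg %*% (kd(Omega, cst$Id1) %*% vec(t(Delta1))))))
  mu2 <- belief2_prev$mu + drive

  list(belief = structure(list(mu = mu2, C = C2, P = P2),
                          class = "gaussian_belief"),
       intermediates = list(PE1 = PE1, Delta1 = Delta1, Omega1_hat = Omega,
                            Lg = Lg, delta1 = delta1, Pi2_hat = Pi2_hat),
       jitter = jit)
}

#' Level-2 variational energy (reference form)
#'
#' The exact expected log-joint as a function of the level-2 state, used as
#' an independent oracle for the closed-form level-2 update: with
#' `A(x2) = epsilon * F2(x2) F2(x2)' + C1_prev` and
#' `M = C1 + PE1 PE1'`,
#' `V2 = -log det A / 2 - tr(A^-1 M) / 2
#'       - (x2 - mu2_prev)' Pi2_hat (x2 - mu2_prev) / 2`.
#' The drive term of the closed-form mean update agrees with the gradient
#' of this function at `mu2_prev` to first order in epsilon.
#'
#' @param x2 Level-2 state vector at which to evaluate.
#' @inheritParams update_level2
#' @return Scalar energy value.
#' @export
variational_energy_V2 <- function(x2, belief2_prev, belief1_prev, belief1_new,
                                  params, config = filter_config()) {
  eps <- config$epsilon
  L <- L1_from_y2(y2_from_x2(x2, params$vol), params$d1)
  A <- eps * tcrossprod(L) + belief1_prev$C
  cholA <- tryCatch(chol(A), error = function(e) {
    stop("variational_energy_V2(): A(x2) is not positive definite", call. = FALSE)
  })
  PE1 <- belief1_new$mu - belief1_prev$mu
  M <- belief1_new$C + tcrossprod(PE1)
  Ainv <- chol2inv(cholA)
  Pi2_hat <- chol_inv(ensure_spd(eps * diag(params$lambda^2, params$d2) +
                                   belief2_prev$C, config$jitter_scale))
  d2v <- x2 - belief2_prev$mu
  -sum(log(diag(cholA))) - 0.5 * sum(Ainv * M) -
    0.5 * drop(crossprod(d2v, Pi2_hat %*% d2v))
}

#' Prediction correlation
#'
#' The model's running estimate of the pairwise coupling between signal
#' dimensions: the prediction covariance (the inverse prediction precision,
#' `epsilon * Sigma1_hat + C1_prev`) normalized to a correlation. For a
#' bivariate signal a scalar in (-1, 1) is returned; for d1 > 2 the full
#' correlation matrix.
#'
#' @param prediction Output of [predict_level1()].
#' @return Scalar correlation (d1 = 2) or correlation matrix (d1 > 2);
#'   `NA` for d1 = 1.
#' @export
prediction_correlation <- function(prediction) {
  S <- prediction$S
  d <- nrow(S)
  if (d < 2) return(NA_real_)
  R <- stats::cov2cor(S)
  if (d == 2) R[1, 2] else R
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# structural constants reused every trial, cached per signal dimension
.d1_cache <- new.env(parent = emptyenv())

d1_constants <- function(d1) {
  key <- as.character(d1)
  out <- .d1_cache[[key]]
  if (is.null(out)) {
    out <- list(Kd = commutation_matrix(d1, d1),
                vecpos = lvec_to_vec_pos(d1),
                isdiag = lvec_is_diag(d1),
                Id1 = diag(d1),
                lower_idx = which(lower.tri(diag(d1), diag = TRUE)),
                krA = rep(seq_len(d1), each = d1),
                krB = rep.int(seq_len(d1), d1))
    .d1_cache[[key]] <- out
  }
  out
}
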