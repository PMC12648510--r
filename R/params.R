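#' Hyperparameters of the two-level hierarchical filter
#'
#' Bundles every native-space hyperparameter of the full model: the
#' observation coupling (w1, b1), the volatility coupling (w2, b2), the
#' second-level diffusion scale lambda (the diagonal of the Cholesky factor
#' of Sigma2, so Sigma2 = diag(lambda^2)), and the prior beliefs over both
#' hidden states. Defaults are the bivariate reference configuration used
#' throughout: w1 = 0.06, b1 = 0, w2 = 0.5, b2 = 0, lambda = 0.02,
#' mu1_0 = (25, 25) with unit prior covariance, mu2_0 = 0 with unit prior
#' covariance.
#'
#' @param d1 Signal dimension (number of observed components).
#' @param w1,b1 Observation coupling strength (> 0) and bias; scalars are
#'   recycled to length d1.
#' @param w2,b2 Volatility coupling strength (> 0) and bias; scalars are
#'   recycled to length d2 = d1(d1+1)/2.
#' @param lambda Positive second-level diffusion scale; recycled to d2.
#' @param mu1_0,mu2_0 Prior means of the hidden states.
#' @param C1_0,C2_0 Prior covariances; a vector is taken as a diagonal.
#' @return An object of class `"hbf_params"`.
#' @export
hbf_params <- function(d1 = 2,
                       w1 = 0.06, b1 = 0,
                       w2 = 0.5, b2 = 0,
                       lambda = 0.02,
                       mu1_0 = 25, C1_0 = 1,
                       mu2_0 = 0, C2_0 = 1) {
  d1 <- as.integer(d1)
  d2 <- d1 * (d1 + 1L) / 2L
  as_cov <- function(C, d) {
    if (is.matrix(C)) {
      stopifnot(nrow(C) == d, ncol(C) == d)
      C
    } else {
      diag(rep_len(as.numeric(C), d), d)
    }
  }
  obs <- observation_coupling(rep_len(w1, d1), rep_len(b1, d1))
  vol <- volatility_coupling(rep_len(w2, d2), rep_len(b2, d2), d1)
  lambda <- rep_len(as.numeric(lambda), d2)
  if (any(lambda <= 0)) stop("lambda must be strictly positive", call. = FALSE)
  structure(list(
    d1 = d1, d2 = d2,
    obs = obs, vol = vol,
    lambda = lambda,
    mu1_0 = rep_len(as.numeric(mu1_0), d1),
    C1_0 = as_cov(C1_0, d1),
    mu2_0 = rep_len(as.numeric(mu2_0), d2),
    C2_0 = as_cov(C2_0, d2)
  ), class = "hbf_params")
}

#' Hyperparameters of the constant-volatility ablation model
#'
#' The ablation model keeps the level-1 update of the full filter but fixes
#' the diffusion matrix at Sigma1 = diag(sigma1) (no second level).
#' Defaults follow the reference configuration: sigma1 = 0.01 (interpreted
#' as a variance), w1 = 0.06, b1 = 0, mu1_0 = (25, 25), C1_0 = 0.25 I.
#'
#' @param d1 Signal dimension.
#' @param sigma1 Positive vector, the fixed diagonal of Sigma1.
#' @param sigma1_as Whether `sigma1` is a `"variance"` (default) or an
#'   `"sd"` whose square enters Sigma1.
#' @inheritParams hbf_params
#' @return An object of class `"ablation_params"`.
#' @export
ablation_params <- function(d1 = 2,
                            w1 = 0.06, b1 = 0,
                            sigma1 = 0.01,
                            mu1_0 = 25, C1_0 = 0.25,
                            sigma1_as = c("variance", "sd")) {
  d1 <- as.integer(d1)
  sigma1_as <- match.arg(sigma1_as)
  sigma1 <- rep_len(as.numeric(sigma1), d1)
  if (any(sigma1 <= 0)) stop("sigma1 must be strictly positive", call. = FALSE)
  if (sigma1_as == "sd") sigma1 <- sigma1^2
  C1_0 <- if (is.matrix(C1_0)) C1_0 else diag(rep_len(as.numeric(C1_0), d1), d1)
  structure(list(
    d1 = d1,
    obs = observation_coupling(rep_len(w1, d1), rep_len(b1, d1)),
    sigma1 = sigma1,
    mu1_0 = rep_len(as.numeric(mu1_0), d1),
    C1_0 = C1_0
  ), class = "ablation_params")
}

#' Numerical configuration of the filter
#'
#' @param epsilon Positive sampling interval between consecutive trials
#'   (default 1).
#' @param jitter_scale Starting jitter for the positive-definiteness guard.
#' @param y2_clamp Bound on the log-space volatility parameters before the
#'   exp/sinh/cosh maps.
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(epsilon = 1, jitter_scale = 1e-10, y2_clamp = 30) {
  stopifnot(epsilon > 0, jitter_scale > 0, y2_clamp > 0)
  structure(list(epsilon = epsilon, jitter_scale = jitter_scale,
                 y2_clamp = y2_clamp),
            class = "filter_config")
}

#' Gaussian belief over a hidden state
#'
#' Posterior mean, covariance and precision of one hidden level at one
#' trial. Exactly one of `C` or `P` may be omitted; the other is filled in
#' by inversion.
#'
#' @param mu Mean vector.
#' @param C Covariance matrix (symmetric positive definite).
#' @param P Precision matrix (inverse of `C`).
#' @return An object of class `"gaussian_belief"`: list with `mu`, `C`, `P`.
#' @export
gaussian_belief <- function(mu, C = NULL, P = NULL) {
  if (is.null(C) && is.null(P)) stop("supply C or P", call. = FALSE)
  if (is.null(P)) P <- chol_inv(ensure_spd(C))
  if (is.null(C)) C <- chol_inv(ensure_spd(P))
  structure(list(mu = as.numeric(mu), C = as.matrix(C), P = as.matrix(P)),
            class = "gaussian_belief")
}
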