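#' Observation-level coupling
#'
#' Parameters of the log-space rate map r0 = exp(W1 x1 + b1): W1 = diag(w1)
#' with positive coupling strengths, b1 a shift. One rate per observed
#' dimension (d0 = d1).
#'
#' @param w1 Positive numeric vector, length d1.
#' @param b1 Numeric vector, same length (default 0).
#' @return An object of class `"observation_coupling"`.
#' @export
observation_coupling <- function(w1, b1 = rep(0, length(w1))) {
  if (length(b1) != length(w1)) stop("w1 and b1 must have equal length", call. = FALSE)
  if (any(w1 <= 0)) stop("all coupling strengths w1 must be > 0", call. = FALSE)
  structure(list(w1 = as.numeric(w1), b1 = as.numeric(b1),
                 d1 = length(w1)),
            class = "observation_coupling")
}

#' Log-density of independent-component multivariate exponential observations
#'
#' The joint log-density of a non-negative vector under independent
#' exponential margins with rate vector r0:
#' `sum(log(r0) - r0 * x0)`. Also the one-step-ahead predictive
#' log-likelihood when evaluated at the predicted rate.
#'
#' @param x0 Non-negative observation vector.
#' @param r0 Strictly positive rate vector, same length.
#' @return The scalar log-density.
#' @export
exp_logpdf <- function(x0, r0) {
  if (length(x0) != length(r0)) stop("dimension mismatch", call. = FALSE)
  if (any(x0 < 0)) stop("observations must be non-negative", call. = FALSE)
  if (any(r0 <= 0)) stop("rates must be strictly positive", call. = FALSE)
  sum(log(r0) - r0 * x0)
}

#' Rate vector from the log-rate state
#'
#' Elementwise `exp(w1 * x1 + b1)`; strictly positive for any finite x1.
#'
#' @param x1 Log-rate state vector, length d1.
#' @param coupling An [observation_coupling()].
#' @return Positive rate vector, length d1.
#' @export
rate_from_x1 <- function(x1, coupling) {
  if (length(x1) != coupling$d1) stop("dimension mismatch", call. = FALSE)
  exp(coupling$w1 * x1 + coupling$b1)
}

#' One-step-ahead rate prediction
#'
#' The predicted rate for the current trial is the rate map evaluated at the
#' previous trial's posterior mean of the log-rate state.
#'
#' @param mu1_prev Previous posterior mean of x1.
#' @inheritParams rate_from_x1
#' @return Positive predicted rate vector.
#' @export
predict_rate <- function(mu1_prev, coupling) {
  rate_from_x1(mu1_prev, coupling)
}

#' Observation-level prediction error
#'
#' `1 - o * r_hat` elementwise: zero exactly when each observation equals
#' the predicted expectation `1/r_hat`; negative when the observation
#' exceeds it (the belief should move the rate down), positive otherwise.
#'
#' @param o Non-negative observation vector.
#' @param r_hat Positive predicted rate vector.
#' @return Prediction-error vector, each component `< 1`.
#' @export
prediction_error0 <- function(o, r_hat) {
  if (length(o) != length(r_hat)) stop("dimension mismatch", call. = FALSE)
  1 - o * r_hat
}

#' One-step-ahead predictive log-likelihood
#'
#' `sum(log(r_hat)) - sum(o * r_hat)`: identical to [exp_logpdf()] at the
#' predicted rate. Summed over trials this is the likelihood entering
#' hyperparameter learning and model comparison.
#'
#' @inheritParams prediction_error0
#' @return Scalar log-likelihood.
#' @export
predictive_loglik <- function(o, r_hat) {
  exp_logpdf(o, r_hat)
}
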