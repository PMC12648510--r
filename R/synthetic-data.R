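# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Cosine benchmark rate trajectory
#'
#' The bivariate benchmark rate course: both dimensions follow
#' `offset + amplitude * cos(2 * pi * cycles * k / K)`; after trial
#' `switch_at` the second dimension flips the sign of its cosine, so the two
#' rates are identical in the first regime and mirror images (summing to
#' `2 * offset`) in the second. With the defaults (K = 400, offset 2.5,
#' amplitude 2, 3.5 cycles, switch after trial 200) the rates stay in
#' [0.5, 4.5].
#'
#' @param K Number of trials (>= 1).
#' @param offset,amplitude Baseline and swing of the rate waveform.
#' @param cycles Number of cosine periods over the K trials (3.5 gives the
#'   `7 * pi * k / K` phase).
#' @param switch_at Last trial of the synchronous regime (default
#'   `ceiling(K / 2)`).
#' @return A K x 2 matrix of positive rates.
#' @export
cosine_rate_trajectory <- function(K, offset = 2.5, amplitude = 2,
                                   cycles = 3.5, switch_at = ceiling(K / 2)) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  k <- seq_len(K)
  wave <- amplitude * cos(2 * pi * cycles * k / K)
  r1 <- offset + wave
  r2 <- ifelse(k <= switch_at, offset + wave, offset - wave)
  matrix(c(r1, r2), ncol = 2, dimnames = NULL)
}

#' Sample independent exponential observations along a rate trajectory
#'
#' One draw `o[k, i] ~ Exponential(rate = rates[k, i])` per entry,
#' reproducible for a given seed (the caller's RNG state is untouched).
#'
#' @param rates K x d matrix of strictly positive rates.
#' @param seed Integer seed.
#' @return K x d matrix of non-negative draws.
#' @export
sample_exponential_series <- function(rates, seed) {
  rates <- as.matrix(rates)
  if (any(rates <= 0)) stop("rates must be strictly positive", call. = FALSE)
  with_seed_(seed, {
    matrix(stats::rexp(length(rates), rate = as.vector(rates)),
           nrow = nrow(rates), ncol = ncol(rates))
  })
}

#' Simulate the cosine benchmark dataset
#'
#' Generates the bivariate benchmark: exponential observations whose rate
#' vector follows [cosine_rate_trajectory()] — synchronous cosines over the
#' first half of the series, anti-synchronous after the regime switch.
#'
#' @inheritParams cosine_rate_trajectory
#' @param seed Integer seed.
#' @return Tibble with columns `trial`, `o1`, `o2` (observations) and
#'   `r1`, `r2` (true rates), plus attributes `seed` and `generator`.
#' @examples
#' dat <- simulate_benchmark(K = 400, seed = 1)
#' head(dat)
#' @export
simulate_benchmark <- function(K = 400, seed = 1, offset = 2.5, amplitude = 2,
                               cycles = 3.5, switch_at = ceiling(K / 2)) {
  rates <- cosine_rate_trajectory(K, offset, amplitude, cycles, switch_at)
  O <- sample_exponential_series(rates, seed)
  out <- tibble::tibble(trial = seq_len(K),
                        o1 = O[, 1], o2 = O[, 2],
                        r1 = rates[, 1], r2 = rates[, 2])
  attr(out, "seed") <- seed
  attr(out, "generator") <- "benchmark"
  out
}

#' Sample from the model's own generative hierarchy
#'
#' Euler-discretized forward simulation of the two-level generative model:
#' the second-level state diffuses as `x2_k = x2_{k-1} + sqrt(eps) * lambda * z`,
#' sets the Cholesky volatility factor `L1_k = F2(x2_k)` (evaluated at the
#' pre-step state within each step), the log-rate state diffuses as
#' `x1_k = x1_{k-1} + sqrt(eps) * L1_k %*% z'`, and observations are
#' exponential draws at `r0_k = exp(W1 x1_k + b1)`. Hidden trajectories are
#' returned for parameter-recovery studies.
#'
#' @param params An [hbf_params()]; the prior means are the initial states.
#' @param K Number of trials.
#' @param seed Integer seed.
#' @param epsilon Sampling interval.
#' @return Tibble with columns `trial`, `o*`, `r*` (true rates), `x1_*`,
#'   `x2_*`, plus attributes `seed` and `generator`.
#' @export
sample_from_hierarchy <- function(params = hbf_params(), K, seed, epsilon = 1) {
  d1 <- params$d1
  d2 <- params$d2
  with_seed_(seed, {
    x1 <- matrix(NA_real_, K, d1)
    x2 <- matrix(NA_real_, K, d2)
    rates <- matrix(NA_real_, K, d1)
    x1k <- params$mu1_0
    x2k <- params$mu2_0
    se <- sqrt(epsilon)
    for (k in seq_len(K)) {
      Lk <- L1_from_y2(y2_from_x2(x2k, params$vol), d1)
      x2k <- x2k + se * params$lambda * stats::rnorm(d2)
      x1k <- x1k + se * drop(Lk %*% stats::rnorm(d1))
      x1[k, ] <- x1k
      x2[k, ] <- x2k
      rates[k, ] <- rate_from_x1(x1k, params$obs)
    }
    O <- matrix(stats::rexp(K * d1, rate = as.vector(rates)), K, d1)
    out <- dplyr::bind_cols(
      tibble::tibble(trial = seq_len(K)),
      mat_cols(O, "o"),
      mat_cols(rates, "r"),
      mat_cols(x1, "x1_"),
      mat_cols(x2, "x2_")
    )
    attr(out, "seed") <- seed
    attr(out, "generator") <- "hierarchy"
    out
  })
}
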