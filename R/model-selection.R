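#' Bayesian information criterion
#'
#' `BIC = dxi * log(K) - 2 * loglik`, with K the number of trials and dxi
#' the number of free hyperparameters; smaller is better.
#'
#' @param loglik Total one-step-ahead predictive log-likelihood at the
#'   fitted hyperparameters.
#' @param dxi Number of free hyperparameters.
#' @param K Number of trials (>= 1).
#' @return Scalar BIC.
#' @export
bic <- function(loglik, dxi, K) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  dxi * log(K) - 2 * loglik
}

#' BIC-approximated Bayes factor
#'
#' `BF(M, Ma) = exp((bic_Ma - bic_M) / 2)`; values above 1 favor the full
#' model M over the ablation Ma.
#'
#' @param bic_M,bic_Ma BIC of the full and ablation model.
#' @return Positive scalar Bayes factor.
#' @export
bayes_factor_bic <- function(bic_M, bic_Ma) {
  exp((bic_Ma - bic_M) / 2)
}

#' Jeffreys evidence category of a Bayes factor
#'
#' Standard bands at 1, 3, 10, 30 and 100.
#'
#' @param bf Positive Bayes factor.
#' @return Ordered factor with the evidence label.
#' @export
jeffreys_label <- function(bf) {
  cut(bf, breaks = c(0, 1, 3, 10, 30, 100, Inf),
      labels = c("negative", "barely worth mentioning", "substantial",
                 "strong", "very strong", "decisive"),
      ordered_result = TRUE)
}

#' Fit and compare the full and ablation models on one dataset
#'
#' Fits both models by free-energy maximization, evaluates each model's
#' total one-step-ahead predictive log-likelihood at its fitted
#' hyperparameters, and compares them by BIC Bayes factor.
#'
#' @param data Data frame of observations, one row per trial.
#' @param config A [filter_config()].
#' @param maxit,laplace Passed to [fit_model()].
#' @param keep_fits Attach the two `hbf_fit` objects as attribute `"fits"`.
#' @return One-row tibble: `loglik_m`, `loglik_ma`, `dxi_m`, `dxi_ma`, `K`,
#'   `bic_m`, `bic_ma`, `bf`, `jeffreys`, `f_m`, `f_ma`, `converged_m`,
#'   `converged_ma`.
#' @export
compare_models <- function(data, config = filter_config(), maxit = 100,
                           laplace = TRUE, keep_fits = FALSE) {
  O <- obs_matrix(data)
  fit_m <- fit_model(data, "full", config = config, maxit = maxit, laplace = laplace)
  fit_ma <- fit_model(data, "ablation", config = config, maxit = maxit, laplace = laplace)
  ll_m <- hbf_engine(O, fit_m$params, config, record = FALSE)$total_loglik
  ll_ma <- ablation_engine(O, fit_ma$params, config, record = FALSE)$total_loglik
  K <- nrow(O)
  bic_m <- bic(ll_m, fit_m$spec$dxi, K)
  bic_ma <- bic(ll_ma, fit_ma$spec$dxi, K)
  bf <- bayes_factor_bic(bic_m, bic_ma)
  ident_resid <- function(fit) {
    if (is.null(fit$F)) return(NA_real_)
    abs(fit$F - negative_free_energy(fit$V_max, fit$C_xi))
  }
  out <- tibble::tibble(
    loglik_m = ll_m, loglik_ma = ll_ma,
    dxi_m = fit_m$spec$dxi, dxi_ma = fit_ma$spec$dxi, K = K,
    bic_m = bic_m, bic_ma = bic_ma, bf = bf,
    jeffreys = as.character(jeffreys_label(bf)),
    f_m = fit_m$F %||% NA_real_, f_ma = fit_ma$F %||% NA_real_,
    bf_fe = if (laplace) exp(fit_m$F - fit_ma$F) else NA_real_,
    v_max_m = fit_m$V_max, v_prior_m = fit_m$V_prior,
    v_max_ma = fit_ma$V_max, v_prior_ma = fit_ma$V_prior,
    f_ident_m = ident_resid(fit_m), f_ident_ma = ident_resid(fit_ma),
    converged_m = fit_m$converged, converged_ma = fit_ma$converged)
  if (keep_fits) attr(out, "fits") <- list(full = fit_m, ablation = fit_ma)
  out
}

#' Replicate benchmark simulations and model comparisons
#'
#' For each replicate, generates a fresh cosine-benchmark dataset with seed
#' `seed_base + rep`, fits both models and records the BIC Bayes factor
#' BF(M, Ma). Replicates whose fit fails are excluded from the summary and
#' counted.
#'
#' @param n_reps Number of replicates (>= 1).
#' @param seed_base Integer; replicate r uses seed `seed_base + r`.
#' @param K Trials per replicate.
#' @param config A [filter_config()].
#' @param maxit,laplace Passed to [fit_model()].
#' @return An object of class `"hbf_replicates"`: list with `results` (one
#'   row per successful replicate), `n_failed`, and the settings.
#'   `glance()` summarizes (median BF, fractions above the Jeffreys bands).
#' @export
run_replicates <- function(n_reps = 20, seed_base = 1, K = 400,
                           config = filter_config(), maxit = 100,
                           laplace = TRUE) {
  stopifnot(n_reps >= 1)
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    seed <- seed_base + r
    row <- tryCatch({
      dat <- simulate_benchmark(K = K, seed = seed)
      cmp <- compare_models(dat, config = config, maxit = maxit, laplace = laplace)
      dplyr::bind_cols(tibble::tibble(rep = r, seed = seed), cmp)
    }, error = function(e) {
      warning("replicate ", r, " failed and was excluded: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(row)) n_failed <- n_failed + 1L else rows[[r]] <- row
  }
  structure(list(results = dplyr::bind_rows(rows), n_failed = n_failed,
                 n_reps = n_reps, seed_base = seed_base, K = K,
                 maxit = maxit),
            class = "hbf_replicates")
}

#' @export
print.hbf_replicates <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<hbf_replicates: %d replicates (%d failed), K = %d>\n",
              x$n_reps, x$n_failed, x$K))
  cat(sprintf("  median BF(M, Ma) = %.3g; fraction BF > 1: %.2f, > 3: %.2f, > 10: %.2f\n",
              g$median_bf, g$frac_bf_gt_1, g$frac_bf_gt_3, g$frac_bf_gt_10))
  invisible(x)
}
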