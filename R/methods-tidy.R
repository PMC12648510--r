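#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-trial trajectory of a filter run
#'
#' @param x An `"hbf_filter"` object.
#' @param ... Unused.
#' @return The per-trial trajectory tibble.
#' @method tidy hbf_filter
#' @export
tidy.hbf_filter <- function(x, ...) {
  x$trajectory
}

#' @rdname tidy.hbf_filter
#' @method glance hbf_filter
#' @export
glance.hbf_filter <- function(x, ...) {
  tibble::tibble(model = x$model,
                 n_trials = nrow(x$trajectory),
                 d1 = x$params$d1,
                 total_pred_loglik = x$total_loglik,
                 n_jitter_events = x$n_jitter_events,
                 n_clamped = x$n_clamped)
}

#' Tidy a hyperparameter fit
#'
#' One row per free-parameter component: the unconstrained estimate, the
#' native-space estimate, the prior mean and standard deviation, and the
#' posterior standard deviation from the Laplace approximation (when
#' available).
#'
#' @param x An `"hbf_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per component of xi.
#' @method tidy hbf_fit
#' @export
tidy.hbf_fit <- function(x, ...) {
  rows <- list()
  pos <- 0L
  for (e in x$spec$entries) {
    if (!e$free) next
    idx <- pos + seq_len(e$len)
    rows[[e$name]] <- tibble::tibble(
      parameter = e$name,
      component = seq_len(e$len),
      estimate = unname(x$mu_xi[idx]),
      estimate_native = transform_param(unname(x$mu_xi[idx]), e$kind, e$alpha),
      prior_mean = e$prior_mean,
      prior_sd = sqrt(e$prior_var),
      posterior_sd = if (is.null(x$C_xi)) NA_real_ else sqrt(diag(x$C_xi)[idx]))
    pos <- pos + e$len
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.hbf_fit
#' @method glance hbf_fit
#' @export
glance.hbf_fit <- function(x, ...) {
  tibble::tibble(model = x$model, dxi = x$spec$dxi, K = x$K,
                 V_max = x$V_max, V_prior = x$V_prior,
                 F = x$F %||% NA_real_,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a replicate experiment
#'
#' @param x An `"hbf_replicates"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per successful replicate. `glance()`: one-row
#'   summary with the median Bayes factor and the fractions exceeding the
#'   Jeffreys bands 1, 3 and 10.
#' @method tidy hbf_replicates
#' @export
tidy.hbf_replicates <- function(x, ...) {
  x$results
}

#' @rdname tidy.hbf_replicates
#' @method glance hbf_replicates
#' @export
glance.hbf_replicates <- function(x, ...) {
  bf <- x$results$bf
  tibble::tibble(n_reps = x$n_reps, n_failed = x$n_failed, K = x$K,
                 median_bf = stats::median(bf),
                 frac_bf_gt_1 = mean(bf > 1),
                 frac_bf_gt_3 = mean(bf > 3),
                 frac_bf_gt_10 = mean(bf > 10))
}
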