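#' Plot a filter run
#'
#' `type = "rates"` shows, per signal dimension, the observations (points),
#' the filtered rate estimate `exp(W1 mu1 + b1)` (line), and the true rate
#' when the data carry `r1..rd` columns (dashed). `type = "correlation"`
#' shows the prediction-correlation trajectory (full model, d1 = 2).
#' `type = "volatility"` shows the second-level means mu2 with a +/- 1 sd
#' band.
#'
#' @param object An `"hbf_filter"` object.
#' @param type One of `"rates"`, `"correlation"`, `"volatility"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbf_filter
#' @export
autoplot.hbf_filter <- function(object, type = c("rates", "correlation", "volatility"),
                                ...) {
  type <- match.arg(type)
  traj <- object$trajectory
  d1 <- object$params$d1
  if (type == "rates") {
    w1 <- object$params$obs$w1
    b1 <- object$params$obs$b1
    long <- purrr::map_dfr(seq_len(d1), function(i) {
      tibble::tibble(
        trial = traj$trial,
        dimension = paste0("dimension ", i),
        observation = traj[[paste0("o", i)]],
        estimate = exp(w1[i] * traj[[paste0("mu1_", i)]] + b1[i]),
        truth = if (paste0("r", i) %in% names(object$data))
          object$data[[paste0("r", i)]] else NA_real_)
    })
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$trial)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$observation),
                          alpha = 0.25, size = 0.6, colour = "steelblue") +
      ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "firebrick") +
      ggplot2::facet_wrap(~dimension, ncol = 1, scales = "free_y") +
      ggplot2::labs(y = "rate", x = "trial",
                    title = "Filtered rate estimate (red) over observations")
    if (!all(is.na(long$truth))) {
      p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$truth),
                                  linetype = "dashed", colour = "black")
    }
    p
  } else if (type == "correlation") {
    if (!"rho1" %in% names(traj)) stop("no prediction correlation in this run",
                                       call. = FALSE)
    ggplot2::ggplot(traj, ggplot2::aes(x = .data$trial, y = .data$rho1)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::labs(y = "prediction correlation", x = "trial")
  } else {
    d2 <- object$params$d2
    if (is.null(d2)) stop("no second level in the ablation model", call. = FALSE)
    long <- purrr::map_dfr(seq_len(d2), function(i) {
      tibble::tibble(trial = traj$trial,
                     component = paste0("mu2[", i, "]"),
                     mean = traj[[paste0("mu2_", i)]],
                     sd = sqrt(traj[[paste0("c2_", i)]]))
    })
    ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           fill = "mistyrose") +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
      ggplot2::labs(y = "log-volatility state", x = "trial")
  }
}

#' Histogram of replicate Bayes factors
#'
#' @param object An `"hbf_replicates"` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of log10 BF(M, Ma) with the
#'   Jeffreys bands at 1, 3 and 10 marked.
#' @method autoplot hbf_replicates
#' @export
autoplot.hbf_replicates <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = log10(.data$bf))) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = log10(c(1, 3, 10)), linetype = "dashed") +
    ggplot2::labs(x = "log10 BF(M, Ma)", y = "replicates",
                  title = "BIC Bayes factors, full vs constant-volatility model")
}
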