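# Extract the observation matrix from a data frame: columns o1..od if
# present, otherwise every numeric column except `trial` and true-rate
# columns r1..rd.
obs_matrix <- function(data) {
  nm <- names(data)
  ocols <- grep("^o[0-9]+$", nm, value = TRUE)
  if (length(ocols) == 0) {
    drop_cols <- c("trial", grep("^r[0-9]+$", nm, value = TRUE),
                   grep("^x[12]_[0-9]+$", nm, value = TRUE))
    ocols <- setdiff(nm[vapply(data, is.numeric, logical(1))], drop_cols)
  } else {
    ocols <- ocols[order(as.integer(sub("^o", "", ocols)))]
  }
  if (length(ocols) == 0) stop("no observation columns found", call. = FALSE)
  O <- as.matrix(data[ocols])
  if (nrow(O) == 0) storage.mode(O) <- "double"
  if (!is.numeric(O) || anyNA(O)) stop("observation columns must be numeric and complete",
                                       call. = FALSE)
  neg <- which(O < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative observation at row %d, column %s",
                 neg[1, 1], ocols[neg[1, 2]]), call. = FALSE)
  }
  O
}

# hot loop of the full two-level filter; record = FALSE skips the
# trajectory bookkeeping (used inside hyperparameter optimization)
hbf_engine <- function(O, params, config, record = TRUE) {
  K <- nrow(O)
  d1 <- params$d1
  d2 <- params$d2
  if (ncol(O) != d1) stop("observations have ", ncol(O), " columns but params$d1 = ",
                          d1, call. = FALSE)
  belief1 <- gaussian_belief(params$mu1_0, C = params$C1_0)
  belief2 <- gaussian_belief(params$mu2_0, C = params$C2_0)
  total_ll <- 0
  n_jitter <- 0L
  n_clamped <- 0L
  if (record) {
    r_hat <- pe0 <- mu1 <- c1d <- pe1 <- matrix(NA_real_, K, d1)
    mu2 <- c2d <- matrix(NA_real_, K, d2)
    rho <- ll <- rep(NA_real_, K)
  }
  for (k in seq_len(K)) {
    o <- O[k, ]
    step <- tryCatch({
      pred <- predict_level1(belief1, belief2, params, config)
      up1 <- update_level1(o, belief1, pred, params, config)
      up2 <- update_level2(belief2, belief1, up1$belief, pred, params, config)
      list(pred = pred, up1 = up1, up2 = up2)
    }, error = function(e) {
      stop("filter diverged at trial ", k, ": ", conditionMessage(e), call. = FALSE)
    })
    llk <- sum(log(step$pred$r_hat)) - sum(o * step$pred$r_hat)
    total_ll <- total_ll + llk
    n_jitter <- n_jitter + (step$pred$jitter > 0) + (step$up2$jitter > 0)
    n_clamped <- n_clamped + step$pred$n_clamped
    if (record) {
      r_hat[k, ] <- step$pred$r_hat
      pe0[k, ] <- step$up1$PE0
      mu1[k, ] <- step$up1$belief$mu
      c1d[k, ] <- diag(step$up1$belief$C)
      pe1[k, ] <- step$up2$intermediates$PE1
      mu2[k, ] <- step$up2$belief$mu
      c2d[k, ] <- diag(step$up2$belief$C)
      rho[k] <- if (d1 == 2) prediction_correlation(step$pred) else NA_real_
      ll[k] <- llk
    }
    belief1 <- step$up1$belief
    belief2 <- step$up2$belief
  }
  out <- list(total_loglik = total_ll, n_jitter_events = n_jitter,
              n_clamped = n_clamped, belief1 = belief1, belief2 = belief2,
              K = K)
  if (record) {
    out <- c(out, list(r_hat = r_hat, PE0 = pe0, mu1 = mu1, c1_diag = c1d,
                       PE1 = pe1, mu2 = mu2, c2_diag = c2d, rho1 = rho,
                       pred_loglik = ll))
  }
  out
}

# constant-volatility baseline: level-1 updates with fixed diagonal Sigma1
ablation_engine <- function(O, params, config, record = TRUE) {
  K <- nrow(O)
  d1 <- params$d1
  if (ncol(O) != d1) stop("observations have ", ncol(O), " columns but params$d1 = ",
                          d1, call. = FALSE)
  belief1 <- gaussian_belief(params$mu1_0, C = params$C1_0)
  Sigma1 <- diag(params$sigma1, d1)
  total_ll <- 0
  n_jitter <- 0L
  if (record) {
    r_hat <- pe0 <- mu1 <- c1d <- matrix(NA_real_, K, d1)
    ll <- rep(NA_real_, K)
  }
  for (k in seq_len(K)) {
    step <- tryCatch({
      S <- config$epsilon * Sigma1 + belief1$C
      Pi1_hat <- guarded_inv(S, config$jitter_scale)
      jit <- attr(Pi1_hat, "jitter") %||% 0
      pred <- list(r_hat = rate_from_x1(belief1$mu, params$obs),
                   Sigma1_hat = Sigma1, S = S, Pi1_hat = Pi1_hat,
                   jitter = jit)
      up1 <- update_level1(O[k, ], belief1, pred, params, config)
      list(pred = pred, up1 = up1)
    }, error = function(e) {
      stop("filter diverged at trial ", k, ": ", conditionMessage(e), call. = FALSE)
    })
    llk <- sum(log(step$pred$r_hat)) - sum(O[k, ] * step$pred$r_hat)
    total_ll <- total_ll + llk
    n_jitter <- n_jitter + (step$pred$jitter > 0)
    if (record) {
      r_hat[k, ] <- step$pred$r_hat
      pe0[k, ] <- step$up1$PE0
      mu1[k, ] <- step$up1$belief$mu
      c1d[k, ] <- diag(step$up1$belief$C)
      ll[k] <- llk
    }
    belief1 <- step$up1$belief
  }
  out <- list(total_loglik = total_ll, n_jitter_events = n_jitter,
              n_clamped = 0L, belief1 = belief1, K = K)
  if (record) {
    out <- c(out, list(r_hat = r_hat, PE0 = pe0, mu1 = mu1, c1_diag = c1d,
                       pred_loglik = ll))
  }
  out
}

mat_cols <- function(M, prefix) {
  colnames(M) <- paste0(prefix, seq_len(ncol(M)))
  tibble::as_tibble(M)
}

#' Run the hierarchical filter over a series of observations
#'
#' Filters a time series of non-negative multivariate observations with the
#' two-level volatility-tracking model: per trial, predictions are formed
#' from the previous posteriors, the level-1 belief over the log-rates is
#' updated by the precision-weighted observation prediction error, and the
#' level-2 belief over the log-space volatility is updated from the level-1
#' belief change.
#'
#' @param data Data frame with one row per trial. Observation columns are
#'   `o1..od` when present, otherwise every numeric column except `trial`
#'   and true-rate columns `r1..rd`.
#' @param params An [hbf_params()] (or [ablation_params()] for
#'   [run_ablation_filter()]).
#' @param config A [filter_config()].
#' @return An object of class `"hbf_filter"`. `tidy()` returns the
#'   per-trial trajectory tibble (predicted rates `r_hat*`, prediction
#'   errors `pe0_*`/`pe1_*`, posterior means `mu1_*`/`mu2_*`, posterior
#'   variances `c1_*`/`c2_*`, prediction correlation `rho1`, per-trial
#'   predictive log-likelihood); `glance()` a one-row summary.
#' @examples
#' dat <- simulate_benchmark(K = 50, seed = 1)
#' fit <- run_hbf_filter(dat)
#' glance(fit)
#' @export
run_hbf_filter <- function(data, params = hbf_params(), config = filter_config()) {
  O <- obs_matrix(data)
  res <- hbf_engine(O, params, config, record = TRUE)
  traj <- dplyr::bind_cols(
    tibble::tibble(trial = seq_len(res$K)),
    mat_cols(O, "o"),
    mat_cols(res$r_hat, "r_hat"),
    mat_cols(res$PE0, "pe0_"),
    mat_cols(res$mu1, "mu1_"),
    mat_cols(res$c1_diag, "c1_"),
    mat_cols(res$PE1, "pe1_"),
    mat_cols(res$mu2, "mu2_"),
    mat_cols(res$c2_diag, "c2_"),
    tibble::tibble(rho1 = res$rho1, pred_loglik = res$pred_loglik)
  )
  structure(list(trajectory = traj, params = params, config = config,
                 model = "full", total_loglik = res$total_loglik,
                 n_jitter_events = res$n_jitter_events,
                 n_clamped = res$n_clamped,
                 belief1 = res$belief1, belief2 = res$belief2,
                 data = data),
            class = "hbf_filter")
}

#' @rdname run_hbf_filter
#' @export
run_ablation_filter <- function(data, params = ablation_params(),
                                config = filter_config()) {
  O <- obs_matrix(data)
  res <- ablation_engine(O, params, config, record = TRUE)
  traj <- dplyr::bind_cols(
    tibble::tibble(trial = seq_len(res$K)),
    mat_cols(O, "o"),
    mat_cols(res$r_hat, "r_hat"),
    mat_cols(res$PE0, "pe0_"),
    mat_cols(res$mu1, "mu1_"),
    mat_cols(res$c1_diag, "c1_"),
    tibble::tibble(pred_loglik = res$pred_loglik)
  )
  structure(list(trajectory = traj, params = params, config = config,
                 model = "ablation", total_loglik = res$total_loglik,
                 n_jitter_events = res$n_jitter_events,
                 n_clamped = 0L,
                 belief1 = res$belief1, belief2 = NULL,
                 data = data),
            class = "hbf_filter")
}

#' @export
print.hbf_filter <- function(x, ...) {
  cat(sprintf("<hbf_filter: %s model, %d trials, d1 = %d>\n",
              x$model, nrow(x$trajectory), x$params$d1))
  cat(sprintf("  total one-step-ahead predictive log-likelihood: %.3f\n",
              x$total_loglik))
  if (x$n_jitter_events > 0 || x$n_clamped > 0) {
    cat(sprintf("  numerical guards: %d jitter events, %d clamped volatility components\n",
                x$n_jitter_events, x$n_clamped))
  }
  invisible(x)
}
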