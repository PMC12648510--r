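#' Parameter transforms between unconstrained and native space
#'
#' Hyperparameter learning runs in an unconstrained (Gaussian-prior) space.
#' Three transform kinds map a value there to its native scale:
#' `"identity"`; `"log"` (native = `exp(g)`, for positive parameters whose
#' prior means are stated as logs); `"sigmoid"` (native =
#' `alpha / (1 + exp(-g))`, for parameters bounded in (0, alpha)).
#'
#' @param g Value in unconstrained space.
#' @param kind One of `"identity"`, `"log"`, `"sigmoid"`.
#' @param alpha Upper bound for the sigmoid transform.
#' @return The native-space value; `untransform()` inverts exactly on the
#'   open range.
#' @export
transform_param <- function(g, kind = c("identity", "log", "sigmoid"), alpha = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         identity = g,
         log = exp(g),
         sigmoid = {
           if (is.null(alpha) || any(alpha <= 0)) stop("sigmoid needs alpha > 0", call. = FALSE)
           alpha / (1 + exp(-g))
         })
}

#' @rdname transform_param
#' @param x Native-space value.
#' @export
untransform_param <- function(x, kind = c("identity", "log", "sigmoid"), alpha = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         identity = x,
         log = {
           if (any(x <= 0)) stop("log-transformed parameters must be positive", call. = FALSE)
           log(x)
         },
         sigmoid = {
           if (is.null(alpha) || any(alpha <= 0)) stop("sigmoid needs alpha > 0", call. = FALSE)
           if (any(x <= 0) || any(x >= alpha)) {
             stop("sigmoid-bounded value outside (0, alpha)", call. = FALSE)
           }
           -log(alpha / x - 1)
         })
}

spec_entry <- function(name, len, kind, prior_mean, prior_var, free, alpha = NULL) {
  list(name = name, len = as.integer(len), kind = kind, alpha = alpha,
       prior_mean = rep_len(prior_mean, len),
       prior_var = rep_len(prior_var, len),
       free = free)
}

#' Hyperparameter table for a model
#'
#' The default prior specification of every hyperparameter: its transform,
#' Gaussian prior mean and (diagonal) covariance in unconstrained space,
#' and whether it is free (enters the optimized vector xi) or fixed (pinned
#' at its unconstrained prior mean). Defaults reproduce the bivariate
#' reference configuration: for the full model the free parameters are
#' mu2_0 (prior N(0, 0.1 I)), mu1_0 (prior N(25, I)) and the log-diagonal
#' of C1_0 (prior N(0, I)), giving dxi = 7; lambda is sigmoid-bounded by
#' 0.04 and w2 by 1, both fixed at their prior means (0.02 and 0.5), w1 is
#' fixed at 0.06 and both biases at 0. For the ablation model the free
#' parameters are mu1_0 and the log-diagonal of C1_0 (prior mean ln 0.25),
#' dxi = 4, with sigma1 fixed at 0.01.
#'
#' @param model `"full"` or `"ablation"`.
#' @param d1 Signal dimension.
#' @return An object of class `"hyper_spec"`: a list of parameter entries
#'   plus `model`, `d1`, `dxi`.
#' @export
hyper_spec <- function(model = c("full", "ablation"), d1 = 2) {
  model <- match.arg(model)
  d1 <- as.integer(d1)
  d2 <- d1 * (d1 + 1L) / 2L
  entries <- if (model == "full") {
    list(
      spec_entry("lambda", d2, "sigmoid", 0, 1, free = FALSE, alpha = 0.04),
      spec_entry("w2",     d2, "sigmoid", 0, 1, free = FALSE, alpha = 1),
      spec_entry("b2",     d2, "identity", 0, 0, free = FALSE),
      spec_entry("mu2_0",  d2, "identity", 0, 0.1, free = TRUE),
      spec_entry("c2G",    d2, "log", 0, 1, free = FALSE),
      spec_entry("mu1_0",  d1, "identity", 25, 1, free = TRUE),
      spec_entry("c1G",    d1, "log", 0, 1, free = TRUE),
      spec_entry("w1",     d1, "log", log(0.06), 0, free = FALSE),
      spec_entry("b1",     d1, "identity", 0, 0, free = FALSE)
    )
  } else {
    list(
      spec_entry("sigma1G", d1, "log", log(0.01), 1, free = FALSE),
      spec_entry("mu1_0",   d1, "identity", 25, 1, free = TRUE),
      spec_entry("c1G",     d1, "log", log(0.25), 1, free = TRUE),
      spec_entry("w1",      d1, "log", log(0.06), 0, free = FALSE),
      spec_entry("b1",      d1, "identity", 0, 0, free = FALSE)
    )
  }
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  structure(list(entries = entries, model = model, d1 = d1,
                 dxi = sum(vapply(entries, function(e) if (e$free) e$len else 0L,
                                  integer(1)))),
            class = "hyper_spec")
}

#' Pack and unpack the free-parameter vector xi
#'
#' `pack_xi()` collects the free parameters' unconstrained values into the
#' named vector xi in spec order; `unpack_xi()` rebuilds the native-space
#' model parameters from xi, pinning fixed parameters at their
#' unconstrained prior means. `prior_mean_xi()` returns the prior mean of
#' xi (the optimizer's starting point).
#'
#' @param values Named list mapping free parameter names to unconstrained
#'   values.
#' @param spec A [hyper_spec()].
#' @return `pack_xi()`/`prior_mean_xi()`: named numeric vector of length
#'   `spec$dxi`. `unpack_xi()`: an [hbf_params()] or [ablation_params()].
#' @export
pack_xi <- function(values, spec) {
  parts <- lapply(spec$entries, function(e) {
    if (!e$free) return(NULL)
    v <- values[[e$name]]
    if (is.null(v)) stop("missing free parameter ", e$name, call. = FALSE)
    stats::setNames(rep_len(v, e$len), paste0(e$name, seq_len(e$len)))
  })
  do.call(c, unname(parts[!vapply(parts, is.null, logical(1))]))
}

#' @rdname pack_xi
#' @export
prior_mean_xi <- function(spec) {
  pack_xi(lapply(spec$entries, `[[`, "prior_mean"), spec)
}

#' @rdname pack_xi
#' @param xi Named numeric vector of length `spec$dxi`.
#' @export
unpack_xi <- function(xi, spec) {
  if (length(xi) != spec$dxi) stop("xi has wrong length", call. = FALSE)
  pos <- 0L
  g <- list()
  for (e in spec$entries) {
    if (e$free) {
      g[[e$name]] <- as.numeric(xi[pos + seq_len(e$len)])
      pos <- pos + e$len
    } else {
      g[[e$name]] <- e$prior_mean
    }
  }
  native <- function(name) {
    e <- spec$entries[[name]]
    transform_param(g[[name]], e$kind, e$alpha)
  }
  d1 <- spec$d1
  if (spec$model == "full") {
    hbf_params(d1 = d1,
               w1 = native("w1"), b1 = native("b1"),
               w2 = native("w2"), b2 = native("b2"),
               lambda = native("lambda"),
               mu1_0 = native("mu1_0"), C1_0 = native("c1G"),
               mu2_0 = native("mu2_0"), C2_0 = native("c2G"))
  } else {
    ablation_params(d1 = d1,
                    w1 = native("w1"), b1 = native("b1"),
                    sigma1 = native("sigma1G"),
                    mu1_0 = native("mu1_0"), C1_0 = native("c1G"))
  }
}

# log prior density of xi: independent Gaussians over the free parameters
log_prior_xi <- function(xi, spec) {
  pos <- 0L
  total <- 0
  for (e in spec$entries) {
    if (!e$free) next
    v <- xi[pos + seq_len(e$len)]
    total <- total + sum(stats::dnorm(v, e$prior_mean, sqrt(e$prior_var), log = TRUE))
    pos <- pos + e$len
  }
  total
}

# sentinel for a diverged filter during optimization
V_DIVERGED <- -1e10

#' Learning objective: penalized predictive log-likelihood
#'
#' The quantity maximized over the free hyperparameters xi: the accumulated
#' one-step-ahead predictive log-likelihood of the filter run at the
#' native-space parameters `unpack_xi(xi)`, plus the Gaussian prior
#' log-density of xi. A diverged filter returns a large negative sentinel
#' so line searches retreat.
#'
#' @param xi Named numeric vector, length `spec$dxi`.
#' @param data Data frame of observations (see [run_hbf_filter()]).
#' @param spec A [hyper_spec()].
#' @param config A [filter_config()].
#' @return Scalar objective value.
#' @export
objective_V <- function(xi, data, spec, config = filter_config()) {
  if (any(!is.finite(xi))) return(V_DIVERGED)
  params <- unpack_xi(xi, spec)
  O <- obs_matrix(data)
  ll <- tryCatch({
    if (spec$model == "full") hbf_engine(O, params, config, record = FALSE)$total_loglik
    else ablation_engine(O, params, config, record = FALSE)$total_loglik
  }, error = function(e) NA_real_)
  if (!is.finite(ll)) return(V_DIVERGED)
  ll + log_prior_xi(xi, spec)
}

# forward-difference gradient (used inside the BFGS line search)
fd_grad <- function(f, x, rel_step = 1e-7) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    h <- rel_step * max(1, abs(x[i]))
    xh <- x
    xh[i] <- xh[i] + h
    (f(xh) - f0) / h
  }, numeric(1))
}

# floor a symmetric matrix's eigenvalues so it is safely positive definite
spd_floor <- function(M, floor = 1e-8) {
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  floored <- any(ee$values < floor)
  vals <- pmax(ee$values, floor)
  list(M = ee$vectors %*% (vals * t(ee$vectors)), floored = floored)
}

# central-difference Hessian with relative step (final Laplace step)
fd_hessian <- function(f, x, rel_step = 1e-4) {
  n <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  shift <- function(i, s) { xi <- x; xi[i] <- xi[i] + s; xi }
  for (i in seq_len(n)) {
    H[i, i] <- (f(shift(i, h[i])) - 2 * f0 + f(shift(i, -h[i]))) / h[i]^2
    if (i < n) for (j in (i + 1):n) {
      xpp <- shift(i, h[i]); xpp[j] <- xpp[j] + h[j]
      xpm <- shift(i, h[i]); xpm[j] <- xpm[j] - h[j]
      xmp <- shift(i, -h[i]); xmp[j] <- xmp[j] + h[j]
      xmm <- shift(i, -h[i]); xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Negative free energy from the Laplace approximation
#'
#' `F = V_max + dxi/2 * log(2*pi*e) + log(det(C_xi))/2`: the evidence lower
#' bound at the Gaussian posterior N(mu_xi, C_xi) over the free
#' hyperparameters.
#'
#' @param V_max Objective value at the optimum.
#' @param C_xi Posterior covariance of xi (symmetric positive definite).
#' @return Scalar negative free energy.
#' @export
negative_free_energy <- function(V_max, C_xi) {
  C_xi <- as.matrix(C_xi)
  ch <- tryCatch(chol(C_xi), error = function(e) {
    stop("C_xi must be positive definite", call. = FALSE)
  })
  dxi <- nrow(C_xi)
  V_max + dxi / 2 * log(2 * pi * exp(1)) + sum(log(diag(ch)))
}

#' Fit hyperparameters by free-energy maximization
#'
#' Maximizes [objective_V()] over the free hyperparameters by BFGS with
#' line search, starting from the prior mean, then takes a Laplace
#' approximation at the optimum: the posterior covariance `C_xi` is the
#' inverse of the negative central-difference Hessian (regularized to be
#' positive definite if needed), and the negative free energy follows from
#' [negative_free_energy()].
#'
#' @param data Data frame of observations, one row per trial.
#' @param model `"full"` or `"ablation"`.
#' @param spec A [hyper_spec()] (defaults to the model's reference table).
#' @param config A [filter_config()].
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance of the line-search BFGS.
#' @param laplace If `FALSE`, skip the Hessian/negative-free-energy step
#'   (faster; `C_xi` and `F` are `NULL`).
#' @return An object of class `"hbf_fit"` with elements `mu_xi`, `C_xi`,
#'   `V_max`, `F`, `V_prior` (objective at the prior mean), `n_iter`,
#'   `converged`, `params` (fitted native-space parameters), `spec`,
#'   `model`, `K`. `tidy()` gives a per-parameter table, `glance()` a
#'   one-row summary.
#' @examples
#' dat <- simulate_benchmark(K = 60, seed = 2)
#' fit <- fit_model(dat, model = "ablation", maxit = 10, laplace = FALSE)
#' glance(fit)
#' @export
fit_model <- function(data, model = c("full", "ablation"),
                      spec = NULL, config = filter_config(),
                      maxit = 100, reltol = 1e-8, laplace = TRUE) {
  model <- match.arg(model)
  O <- obs_matrix(data)
  if (is.null(spec)) spec <- hyper_spec(model, d1 = ncol(O))
  stopifnot(spec$model == model)
  fn <- function(xi) objective_V(xi, data, spec, config)
  x0 <- prior_mean_xi(spec)
  V_prior <- fn(x0)
  opt <- stats::optim(x0, fn, gr = function(x) fd_grad(fn, x),
                      method = "BFGS",
                      control = list(fnscale = -1, maxit = maxit, reltol = reltol))
  mu_xi <- opt$par
  V_max <- opt$value
  C_xi <- Fval <- NULL
  hessian_floored <- FALSE
  if (laplace) {
    H <- fd_hessian(fn, mu_xi)
    negH <- spd_floor(-H)
    hessian_floored <- negH$floored
    C_xi <- chol_inv(ensure_spd(negH$M))
    dimnames(C_xi) <- list(names(mu_xi), names(mu_xi))
    Fval <- negative_free_energy(V_max, C_xi)
  }
  structure(list(mu_xi = mu_xi, C_xi = C_xi, V_max = V_max, F = Fval,
                 V_prior = V_prior,
                 n_iter = unname(opt$counts["function"]),
                 converged = opt$convergence == 0,
                 hessian_floored = hessian_floored,
                 params = unpack_xi(mu_xi, spec),
                 spec = spec, model = model, K = nrow(O),
                 seed = attr(data, "seed")),
            class = "hbf_fit")
}

#' @export
print.hbf_fit <- function(x, ...) {
  cat(sprintf("<hbf_fit: %s model, dxi = %d, K = %d trials>\n",
              x$model, x$spec$dxi, x$K))
  cat(sprintf("  V(mu_xi) = %.4f (prior mean: %.4f); converged: %s\n",
              x$V_max, x$V_prior, x$converged))
  if (!is.null(x$F)) cat(sprintf("  negative free energy F = %.4f\n", x$F))
  invisible(x)
}
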