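test_that("parameter transforms invert exactly on their ranges", {
  expect_equal(transform_param(log(0.06), "log"), 0.06)
  expect_equal(transform_param(0, "sigmoid", alpha = 0.04), 0.02)
  expect_equal(transform_param(1.3, "identity"), 1.3)
  expect_error(untransform_param(0.05, "sigmoid", alpha = 0.04), "outside")
  expect_error(untransform_param(-1, "log"), "positive")
  set.seed(22)
  g <- rnorm(100, sd = 2)
  for (kind in c("identity", "log")) {
    expect_equal(untransform_param(transform_param(g, kind), kind), g,
                 tolerance = 1e-12)
  }
  expect_equal(untransform_param(transform_param(g, "sigmoid", 0.04), "sigmoid", 0.04),
               g, tolerance = 1e-9)
})

test_that("the default tables give dxi = 7 (full) and 4 (ablation) and the reference values", {
  sp <- hyper_spec("full")
  expect_equal(sp$dxi, 7L)
  expect_equal(sp$entries$lambda$alpha, 0.04)
  expect_equal(sp$entries$w2$alpha, 1)
  expect_equal(sp$entries$mu1_0$prior_mean, c(25, 25))
  expect_equal(sp$entries$mu2_0$prior_var, rep(0.1, 3))
  expect_equal(sp$entries$w1$prior_mean, rep(log(0.06), 2))

  spa <- hyper_spec("ablation")
  expect_equal(spa$dxi, 4L)
  expect_equal(spa$entries$sigma1G$prior_mean, rep(log(0.01), 2))
  expect_equal(spa$entries$c1G$prior_mean, rep(log(0.25), 2))

  # unpacking the prior mean reproduces the reference parameter objects
  p <- unpack_xi(prior_mean_xi(sp), sp)
  expect_equal(p$lambda, rep(0.02, 3))
  expect_equal(p$vol$w2, rep(0.5, 3))
  expect_equal(p$obs$w1, rep(0.06, 2))
  expect_equal(p$mu1_0, c(25, 25))
  expect_equal(p$C1_0, diag(2))
  expect_equal(p$C2_0, diag(3))
  pa <- unpack_xi(prior_mean_xi(spa), spa)
  expect_equal(pa$sigma1, rep(0.01, 2))
  expect_equal(pa$C1_0, 0.25 * diag(2))
})

test_that("pack/unpack round-trips and fixed parameters never enter xi", {
  sp <- hyper_spec("full")
  xi <- prior_mean_xi(sp)
  expect_equal(length(xi), 7L)
  expect_named(xi, c("mu2_01", "mu2_02", "mu2_03", "mu1_01", "mu1_02",
                     "c1G1", "c1G2"))
  vals <- list(mu2_0 = c(0.1, -0.2, 0.3), mu1_0 = c(24, 26), c1G = c(0.5, -0.5))
  xi2 <- pack_xi(vals, sp)
  p <- unpack_xi(xi2, sp)
  expect_equal(p$mu2_0, vals$mu2_0)
  expect_equal(p$mu1_0, vals$mu1_0)
  expect_equal(diag(p$C1_0), exp(vals$c1G))
  # fixed parameters stay pinned regardless of xi
  expect_equal(p$lambda, rep(0.02, 3))
})

test_that("the objective is the filter's predictive likelihood plus the prior", {
  sp <- hyper_spec("full")
  xi <- prior_mean_xi(sp)

  # no observations: the objective reduces to the prior log-density
  empty <- tibble::tibble(o1 = numeric(0), o2 = numeric(0))
  expect_equal(objective_V(xi, empty, sp), log_prior_xi(xi, sp))

  dat <- simulate_benchmark(K = 40, seed = 4)
  v <- objective_V(xi, dat, sp)
  run <- run_hbf_filter(dat, unpack_xi(xi, sp))
  expect_equal(v, run$total_loglik + log_prior_xi(xi, sp), tolerance = 1e-10)
  # deterministic
  expect_identical(v, objective_V(xi, dat, sp))
  # non-finite xi retreats to the sentinel
  expect_equal(objective_V(replace(xi, 1, NaN), dat, sp), -1e10)
})

test_that("negative free energy follows the Laplace closed form", {
  expect_equal(negative_free_energy(0, matrix(1)), 0.5 * log(2 * pi * exp(1)))
  expect_equal(negative_free_energy(0, matrix(1)), 1.41894, tolerance = 1e-5)
  # doubling the covariance adds dxi/2 * log 2
  C <- diag(3) * 0.7
  expect_equal(negative_free_energy(1, 2 * C) - negative_free_energy(1, C),
               3 / 2 * log(2))
  expect_error(negative_free_energy(0, matrix(-1)), "positive definite")
})

test_that("the finite-difference Hessian recovers a quadratic's curvature exactly", {
  # V(xi) = -xi' A xi / 2 has Hessian -A everywhere
  A <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  f <- function(x) -0.5 * drop(t(x) %*% A %*% x)
  H <- fd_hessian(f, c(0.3, -0.2))
  expect_equal(H, -A, tolerance = 1e-6)
  # Laplace step on the scalar unit-curvature case
  H1 <- fd_hessian(function(x) -0.5 * x^2, 0)
  expect_equal(negative_free_energy(0, solve(-H1)), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-6)
})

test_that("fitting improves the objective and satisfies the free-energy identity", {
  dat <- simulate_benchmark(K = 60, seed = 6)
  fit <- fit_model(dat, "ablation", maxit = 15)
  expect_s3_class(fit, "hbf_fit")
  expect_gte(fit$V_max, fit$V_prior)
  expect_equal(fit$F,
               fit$V_max + fit$spec$dxi / 2 * log(2 * pi * exp(1)) +
                 0.5 * determinant(fit$C_xi)$modulus[[1]])
  expect_no_error(chol(fit$C_xi))
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_true(all(is.finite(td$posterior_sd)))
  g <- glance(fit)
  expect_equal(g$dxi, 4L)
  expect_true(g$converged %in% c(TRUE, FALSE))
})

test_that("fitting moves the initial rate belief toward the data's early mean", {
  # data simulated at a rate well below the prior-mean initial prediction
  set.seed(30)
  K <- 60
  rates <- matrix(1.0, K, 2)
  O <- sample_exponential_series(rates, seed = 31)
  dat <- tibble::tibble(o1 = O[, 1], o2 = O[, 2])
  fit <- fit_model(dat, "ablation", maxit = 20, laplace = FALSE)
  # prior-mean initial rate is exp(0.06 * 25) ~ 4.48; truth is 1.0
  r0_fit <- rate_from_x1(fit$params$mu1_0, fit$params$obs)
  expect_true(all(r0_fit < exp(1.5)))
})
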