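# shared fixtures, built in code

# random symmetric positive-definite matrix
rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) / d * scale + diag(d) * 0.1
}

# random beliefs + predictions for one trial of the bivariate model
random_trial <- function(d1 = 2, params = hbf_params(d1 = d1),
                         config = filter_config()) {
  d2 <- d1 * (d1 + 1) / 2
  b1 <- gaussian_belief(rnorm(d1), C = rand_spd(d1))
  b2 <- gaussian_belief(rnorm(d2, sd = 0.5), C = rand_spd(d2, 0.3))
  pred <- predict_level1(b1, b2, params, config)
  o <- rexp(d1, rate = pred$r_hat)
  list(b1 = b1, b2 = b2, pred = pred, o = o, params = params, config = config)
}

# central-difference gradient with explicit step
cd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
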