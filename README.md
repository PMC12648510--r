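# expvol

Online hierarchical Bayesian filtering of volatile multivariate
exponential signals.

Many signals of interest in neuroscience and beyond — interspike
intervals, episode durations, waiting times, amplitude envelopes — are
non-negative and exponentially distributed: peakless, heavy-tailed, with
the standard deviation equal to the mean, and memoryless, so each new
observation constrains the next one only weakly. When the underlying rate
parameter also drifts over time, and the drifts of different signal
dimensions are *correlated*, both the rates and their time-varying
correlation structure have to be estimated trial by trial. `expvol` is
for analysts who need exactly that: an online filter for
$o_k \in \mathbb{R}_{\ge 0}^{d}$ with

$$o_k(i) \sim \mathrm{Exp}\!\big(r_{0,k}(i)\big), \qquad
  r_{0,k} = \exp(W_1 x_{1,k} + b_1),$$

where the log-rate state $x_1$ is a Brownian motion whose diffusion
matrix $\Sigma_1 = L_1 L_1^\top$ is itself driven by a second-level
Brownian motion $x_2$ through a log-space Cholesky parameterization
(diagonal of $L_1$: $\exp$; off-diagonal: $2\sinh$). Trial-by-trial
variational updates take closed form: the level-1 belief moves by the
precision-weighted prediction error $1 - o_k \odot \hat r_{0,k}$, and the
level-2 belief performs an exact Newton step on its variational energy,
tracking volatility and the pairwise *prediction correlation* of the
signal. Hyperparameters are learned by BFGS maximization of the negative
free energy with a Laplace approximation, and the model is compared
against a constant-volatility ablation by BIC Bayes factors.

## Worked example

Simulate the bivariate cosine benchmark (two exponential channels whose
rates move synchronously for 200 trials, then mirror each other), filter
it, and inspect the result:

```r
library(expvol)

dat <- simulate_benchmark(K = 400, seed = 1)
fit <- run_hbf_filter(dat)
glance(fit)
#> # A tibble: 1 × 6
#>   model n_trials    d1 total_pred_loglik n_jitter_events n_clamped
#>   <chr>    <int> <int>             <dbl>           <int>     <int>
#> 1 full       400     2             -442.               0         0

tail(tidy(fit)[, c("trial", "o1", "r_hat1", "r_hat2", "mu2_2", "rho1")], 3)
#> # A tibble: 3 × 6
#>   trial     o1 r_hat1 r_hat2 mu2_2   rho1
#>   <int>  <dbl>  <dbl>  <dbl> <dbl>  <dbl>
#> 1   398 1.09     1.31   3.75 0.104 0.0365
#> 2   399 3.05     1.29   3.52 0.110 0.0378
#> 3   400 0.0621   1.15   3.22 0.111 0.0378
```

`total_pred_loglik` is the accumulated one-step-ahead predictive
log-likelihood (the quantity hyperparameter learning maximizes);
`r_hat1`/`r_hat2` are the predicted rates — at trial 400 the truth is
(0.5, 4.5), and the filter sits at (1.15, 3.22), trailing the cosine by
its smoothing window as it must under exponential noise. `mu2_2` is the
off-diagonal volatility state and `rho1` the prediction correlation the
model has inferred between the two channels; zero jitter/clamp events
mean no numerical guard fired. `autoplot(fit)`,
`autoplot(fit, type = "correlation")` and
`autoplot(fit, type = "volatility")` plot the trajectories.

Hyperparameter learning and model comparison:

```r
fit2 <- fit_model(dat, model = "full", maxit = 20)
glance(fit2)          # V_max, negative free energy F, convergence

reps <- run_replicates(n_reps = 10, seed_base = 1, K = 400, maxit = 20)
glance(reps)          # median BF(M, Ma) and Jeffreys-band fractions
autoplot(reps)        # histogram of log10 Bayes factors
```

On this benchmark the full model beats the constant-volatility ablation
decisively (median Bayes factors of order 10^60; the ablation cannot
raise its fixed diffusion to follow the moving rates).

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/scripts/expvol simulate --benchmark cosine --K 400 --seed 1 --out data.csv
Rscript inst/scripts/expvol filter   --in data.csv --out trajectory.csv
Rscript inst/scripts/expvol compare  --in data.csv --out comparison.json
```

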