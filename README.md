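# snapfilter

Scalable Bayesian inference for nonlinear mixed-effects (NLME) models from
**snapshot** time-series data — datasets in which every individual (a cell
in a flow-cytometry experiment, a patient with a single biopsy) is measured
exactly once.

## The problem and the method

An NLME model couples a deterministic time-series model
`ybar(psi, t)` for one individual, an error model for measurement noise,
and a population model `p(psi | theta)` for the inter-individual
variability (IIV) of the individual-level parameters `psi`. The traditional
Bayesian treatment samples the joint posterior of the population parameters
`theta` and one latent `psi_i` per measured individual,

```
log p(D, Psi | theta) = sum_ij log p(y_ij | psi_i, t_j)
                      + sum_i  log p(psi_i | theta),
```

which costs one trajectory simulation per individual per likelihood
evaluation — intractable for the thousands of individuals that
high-throughput snapshot assays produce.

**Filter inference** replaces the population measurement distribution at
each time point with a *filter*: an approximate density built from `S`
simulated individuals,

```
log p(D | theta)  ~  sum_ij log p(y_ij | Ytilde_j(theta)),
```

so each likelihood evaluation costs `S` trajectory simulations regardless
of the dataset size. Five filter families are provided — Gaussian,
lognormal, Gaussian mixture (M kernels), Gaussian KDE and lognormal KDE
(rule-of-thumb bandwidth `b^2 = (4/3S)^(2/5) var`) — each with exact
gradients with respect to the data point and every simulated measurement.

Because re-simulating `Ytilde` at each proposal makes the estimate
stochastic, the package also implements the **deterministic hierarchical
form** over the extended state `(theta, Ytilde, Psi~)`,

```
log p(D, Ytilde, Psi~ | theta) = sum_ij log p(y_ij | Ytilde_j)
                               + sum_sj log p(ytilde_sj | psi_s, t_j)
                               + sum_s  log p(psi_s | theta),
```

a differentiable density sampled efficiently with the built-in No-U-Turn
sampler; marginalising to `theta` gives the same posterior as the
stochastic form.

Three study systems ship with seeded generators: early exponential cancer
growth (Gaussian noise), a two-state EGF receptor signalling model solved
in closed form (lognormal noise, two observables, two exposure
concentrations), and a bimodal two-variant cancer model with a
covariate-shifted growth rate.

## Worked example

Infer the cancer growth population parameters from 90 snapshot
measurements with a Gaussian filter and `S = 100` simulated individuals:

```r
library(snapfilter)

d     <- generate_cancer(m = 1, seed = 1)     # 90 individuals, 6 times
model <- get_model("cancer")
prior <- default_prior("cancer")

post  <- filter_posterior(d, model, filter_spec("gaussian"), prior, S = 100)
post$dim
#> [1] 805

set.seed(1)
chain <- sample_posterior(post, "nuts", x0 = post$init(),
                          n_warmup = 200, n_main = 300)
theta <- theta_draws(chain, post)
round(colMeans(theta), 3)
#>        mu_y0     sigma_y0    mu_lambda sigma_lambda     mu_sigma
#>        9.998        0.737        2.027        0.573        0.770
round(apply(theta, 2, credible_interval), 2)
#>      mu_y0 sigma_y0 mu_lambda sigma_lambda mu_sigma
#> [1,]  9.62     0.36      1.82         0.46     0.56
#> [2,] 10.39     1.12      2.22         0.73     0.99

x <- post$init(seed = 2)
reset_eval_count(model)
lp <- post$lp(x)
eval_count(model)
#> [1] 100
```

The data were generated with `theta = (10, 1, 2, 0.5, 0.8)`: the 90%
credible intervals cover the data-generating means and spreads, and the
noise marginal `mu_sigma` stays close to its prior — with snapshot data,
observed variability cannot be split between IIV and noise, which is why
an informative noise prior matters. The extended state has
`5 + 100*2 + 100*6 = 805` dimensions, yet each posterior evaluation costs
exactly `S = 100` trajectory simulations, independent of the number of
measured individuals.

Higher-level drivers reproduce the full study designs:
`run_cancer_comparison()` (filter inference versus the traditional
hierarchical baseline), `run_egf()` (pooled low/high-EGF datasets,
kon–koff identifiability), `run_filter_bias_study()` (filter choice on the
bimodal model) and `run_S_sweep()` (information loss versus `S`).

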