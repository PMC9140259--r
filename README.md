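# sbel: spatial Bayesian empirical likelihood models for small-area data

`sbel` fits semi-parametric Bayesian models for areal (small-area) data
— disease mapping being the canonical use — without assuming a
parametric distribution for the response. The data model is a
Fay–Herriot structure

    Y_i = mu_i + eps_i,    mu_i = x_i' beta + psi_i,

with the likelihood replaced by an **empirical likelihood** (EL):
weights `w_i` maximise `sum(log w_i)` subject to

    sum(w_i) = 1,   sum(w_i (y_i - mu_i)) = 0,
    sum(w_i (y_i - mu_i)^2 / sigma_i^2) = 1,

and `prod(w_i)` enters the posterior in place of a density. Spatial
structure comes from parametric priors on the area random effects
`psi`: independent Gaussian (IG), intrinsic CAR (BYM), the Leroux
family with mixing parameter `rho` in [0, 1], or a reduced-rank
generalised Moran eigenvector basis. Models are fitted by a block
random-walk Metropolis–Hastings sampler in which any proposal whose EL
constraints are unsatisfiable is rejected; `rho` is chosen by grid
search under the stable (variance-penalty) WAIC, and convergence is
assessed by the Gelman–Rubin diagnostic.

The audience is analysts of small-area health or surveillance data who
want spatial smoothing and covariate inference when the usual Gaussian
or Poisson assumptions for the (log) standardised incidence ratio look
doubtful — few areas, outliers, or mixture-like responses.

## Worked example

Simulate a 25-area lattice scenario with strong spatial autocorrelation
and fit the SBEL model with an independent-Gaussian prior:

```r
library(sbel)

sim <- generate_scenario(scenario_spec(25, "high", seed = 1))
fit <- sbel(sim$data, prior = "ig",
            config = sampler_config(n_iter = 20000, burn_in = 2000,
                                    thin = 10, n_chains = 3,
                                    pilot_length = 2000, seed = 1))
fit
```

```
SBEL fit: ig prior | 5400 pooled draws | WAIC = 169.50
 parameter  mean ci_low ci_high psrf
     beta0 0.208 0.0556   0.359    1
     beta1 0.477 0.2600   0.707    1
       tau 6.300 2.9300  11.100    1
```

Reading the output: `beta1` is the covariate effect on the log relative
risk (true value 0.5 here, comfortably inside the 95% credible
interval); `beta0` absorbs the intercept together with the overall
level of the spatial field, which is not separately identifiable;
`tau` is the prior precision of the random effects. PSRF values near 1
indicate the three chains agree. The WAIC sits a few units above the
analytic EL floor `2 n log n = 160.94` — for EL models the pointwise
log-likelihood is the log weight `log(w_i)`, whose draws hover around
`log(1/n)`, so WAIC values are read as floor + lack-of-fit + penalty.
`fit$smoothed` contains posterior summaries of the smoothed values
`exp(mu_i)` per area, and `write_fit_csv(fit, dir)` exports everything
as CSV.

To select the Leroux mixing parameter:

```r
gs <- grid_search_rho(sim$data, config = sampler_config(
        n_iter = 5000, burn_in = 1000, thin = 5, n_chains = 1,
        pilot_length = 1000, seed = 1),
        rho_grid = c(0, 0.3, 0.6, 0.9))
gs$best_rho    # rho minimising WAIC
gs$table       # per-rho WAIC table
```

A command-line interface wraps the same functions
(`inst/scripts/sbel.R`): `simulate` writes a scenario as CSV + GAL
files, `fit` fits any of the four priors to an area table + adjacency
file, `diagnose` re-checks convergence of a finished fit directory.

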