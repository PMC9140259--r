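---
title: "Spatial Bayesian empirical likelihood for small-area data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Bayesian empirical likelihood for small-area data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbel)
```

## The model

`sbel` fits area-level small-area models of Fay--Herriot type,

$$Y_i = \mu_i + \epsilon_i, \qquad \mu_i = x_i'\beta + \psi_i,$$

where $Y_i$ is a continuous summary for area $i$ (typically a log
standardised incidence ratio), $\beta$ are fixed covariate effects and
$\psi_i$ is a spatially structured random effect. No parametric
distribution is assumed for $Y_i$. Instead the data likelihood is an
empirical likelihood (EL): probability weights $w_i$ on the observed
areas maximise $\sum_i \log w_i$ subject to

$$\sum_i w_i = 1,\qquad
  \sum_i w_i (y_i - \mu_i) = 0,\qquad
  \sum_i w_i (y_i - \mu_i)^2/\sigma_i^2 = 1,$$

and $\prod_i w_i$ replaces the likelihood in the posterior
$p(\beta, \psi, \tau \mid Y) \propto \prod_i w_i(\beta,\psi)\,
\pi(\psi \mid \tau)\,\pi(\beta \mid \tau)\,\pi(\tau)$. The first
constraint centres the weighted residuals; the second calibrates their
weighted spread against the per-area sampling variances $\sigma_i^2$.
When $\sigma_i^2$ are not supplied, the constant residual variance of
the weighted-least-squares (WLS) fit is used for every area.

The EL weight solver works in the standard dual: $w_i = 1/\{n(1 +
\lambda' f_i)\}$ with $f_i = (r_i, r_i^2/\sigma_i^2 - 1)'$, and a damped
Newton iteration locates the two-dimensional multiplier $\lambda$. A
proposal for which the origin lies outside the convex hull of the
$\{f_i\}$ (or for which Newton cannot satisfy the constraints) has no EL
solution; the sampler treats that exactly as a rejected move rather
than an error. An exponential-tilting variant (weights
$w_i \propto e^{\lambda' f_i}$) is available through
`solve_el(type = "et")`; the Owen form is the default because it is what
the common EL software computes and what the reference analyses used.

## Spatial priors

Four families of priors for $\psi$ are supported, all Gaussian kernels
$\propto \exp(-\tfrac{1}{2}\tau\, \psi' Q_0\, \psi)$ with precision
scale $\tau$:

* **Independent Gaussian (IG):** $Q_0 = I$. No spatial structure.
* **Intrinsic CAR / BYM:** $Q_0 = R$, the intrinsic autoregression
  matrix ($R_{ii} = n_i$ neighbours, $R_{ij} = -1$ for adjacent pairs).
  Improper: rank $n - c$ for $c$ graph components.
* **Leroux:** $Q_0 = (1-\rho) I + \rho R$ with mixing parameter
  $\rho \in [0,1]$ interpolating between the two previous cases. Its
  full conditionals have mean
  $\rho \sum_{j \sim i} \psi_j / (n_i \rho + 1 - \rho)$ and variance
  $\sigma^2 / (n_i \rho + 1 - \rho)$; these closed forms are used as a
  test oracle, never in the sampler itself.
* **Moran basis:** a reduced-rank alternative. The adjacency operator is
  residualised against the design, $P_c = I - X(X'X)^{-1}X'$, and the
  eigenvectors of $P_c B P_c$ with positive eigenvalues form an
  orthonormal basis $M$ (dimension $q < n$). The random effect is
  $\psi = M\psi^*$ with prior precision $\tau\,M'(B_+ - B)M$. The
  "non-zero eigenvalue" cutoff is $10^{-8}$ times the largest
  eigenvalue; only positive eigenvalues (positive spatial
  autocorrelation patterns) are retained, following standard practice
  for this basis.

The coefficient prior is a Zellner-style Gaussian anchored at the WLS
estimate, $\beta \sim N(\beta_{WLS}, (g\tau)^{-1} I)$, with $g = 10$ by
default (roughly 10% prior weight); the WLS weights are $1/\sigma_i^2$
when per-area variances are supplied and unit otherwise. The precision
prior is Gamma-type. Two parameterisations of its kernel are
implemented: the default `as_printed` uses
$\pi(\tau) \propto \tau^{1+\alpha_1} e^{-\alpha_2 \tau}$
(with $\alpha_1 = \alpha_2 = 1$), reproducing the kernel used by the
reference analyses; `standard_gamma` uses the textbook
$\tau^{\alpha_1 - 1} e^{-\alpha_2 \tau}$.

### The $\tau$-power factors

The Gaussian kernels for $\psi$ and $\beta$ carry normalisation factors
$\tau^{k/2}$ and $\tau^{(p+1)/2}$ (with $k$ the rank of $Q_0$). These
cancel in the $\psi$ and $\beta$ Metropolis ratios, where $\tau$ is
fixed, but not in the $\tau$ update. `hyperparams(include_tau_power =
TRUE)` (the default) includes them, which makes the $\tau$ full
conditional the proper high-shape Gamma
$$\tau \mid \cdot \;\sim\; \mathrm{Gamma}\!\left(\alpha_1 + 2 +
  \tfrac{k}{2} + \tfrac{p+1}{2},\;
  \alpha_2 + \tfrac{1}{2}\psi' Q_0 \psi +
  \tfrac{g}{2}\|\beta - \beta_{WLS}\|^2\right)$$
under the `as_printed` mode (the "+2" is that mode's extra
$\tau$-power). This closed form is derived symbolically from the
kernels and verified by a prior-only sampling test. We evaluated the
alternative (dropping the powers, giving a shape-$\,\alpha_1\!+\!2$
conditional): it collapses $\tau$ towards zero, frees the random
effects almost completely and degrades the fit badly (the WAIC penalty
grows several-fold), and it is inconsistent with the narrow precision
credible intervals the method is known to produce. Both behaviours
remain switchable.

## The sampler

Fitting uses a block random-walk Metropolis--Hastings scheme:

1. **Initialisation.** $\beta$ starts at its maximum empirical
   likelihood estimate (Nelder--Mead seeded at $\beta_{WLS}$, falling
   back to $\beta_{WLS}$ if the search fails); $\psi = 0$; $\tau$ is
   drawn from its prior; $w_i = 1/n$.
2. **$\psi$ update.** An all-at-once multivariate Gaussian random-walk
   proposal. The EL weights are recomputed at the proposal; an
   infeasible proposal is rejected outright, otherwise the acceptance
   ratio is the product of the EL ratio and the spatial prior ratio.
   By default the EL moments in this block evaluate $\mu$ at the
   *initial MELE* of $\beta$ (`psi_moment_beta = "mele"`), mirroring
   the reference algorithm; the internally coherent alternative of
   using the current $\beta$ is available (`"current"`). In mele mode
   an accepted $\psi$ must also be feasible at the current $\beta$, so
   that every stored draw satisfies the constraint set.
3. **$\beta$ update.** Gaussian random walk centred at the current
   value, EL-gated in the same way, with the Zellner prior ratio.
   (Describing both updates as random walks is required for the
   correction-free acceptance ratios to be valid; independence
   proposals would need Hastings terms.)
4. **$\tau$ update.** Scalar Gaussian random walk; negative proposals
   are rejected; the EL term cancels. The ratio uses the $\psi$, $\beta$
   and $\tau$ kernels with the power factors as configured.

Proposal scales are tuned by a two-stage pilot phase: scalar multipliers
adapt towards an acceptance band of 0.2--0.4, then the proposal
covariances are rebuilt from the pilot draws (scaled by $2.38^2/d$) and
the multipliers re-adapt. All adaptation is frozen before the retained
phase, so the retained kernel is a valid fixed Metropolis kernel.
Chains are reproducible: the same data, configuration and seed yield
identical draws.

$\rho$ is *not* sampled — the EL posterior carries too little
information to separate it from $\psi$, and joint sampling mixes very
poorly — but chosen by grid search: `grid_search_rho()` fits the model
at each candidate (default grid $0, 0.1, \ldots, 0.9, 0.95, 0.99, 1$)
and ranks the fits by WAIC. The endpoints of the grid reproduce the IG
and BYM models exactly (bitwise, at matched seeds).

The full-scale protocol of the reference analyses (three chains of one
million iterations, 100,000 burn-in, thinning 10) is the package
default; every analysis in the tests and the acceptance script scales
this down (typically 20,000 iterations, 10% burn-in, thinning 10, three
chains for headline fits; shorter single chains inside replicate
studies), which the convergence diagnostics on these small lattices
support.

## Model comparison and diagnostics

The pointwise log-likelihood contribution of area $i$ at a stored draw
is $\log w_i$ — the log EL weight, not $\log(n w_i)$. This convention is
fixed by the arithmetic of the method's published WAIC values, which sit
just above the analytic floor $2 n \log n$ (450.84 at $n = 56$); since
adding a constant to every pointwise contribution shifts only the lppd
and not the penalty, the choice cannot affect model rankings. WAIC uses
the stable variance-based penalty: $\mathrm{lppd} = \sum_i \log
\bar{w}_i$ (log-sum-exp over draws), $p_{waic} = \sum_i
\mathrm{Var}_t(\log w_{ti})$, $\mathrm{WAIC} = -2(\mathrm{lppd} -
p_{waic})$. For EL fits Jensen's inequality gives
$\mathrm{lppd} \le -n\log n$ always.

Convergence is assessed post hoc with the classic Gelman--Rubin
potential scale reduction factor over the parallel chains (clamped below
at 1); rank-normalised variants are deliberately not used, to match the
method's era. Posterior summaries are pooled across chains;
credible intervals are equal-tailed percentile intervals (the HPD
alternative is not offered). Smoothed area values are summarised as
$e^{\mu_i}$ per draw.

## The synthetic-data generator

`generate_scenario()` emulates lattice disease-mapping data: a proper
Leroux Gaussian field $\psi$ with mixing parameter $\rho_{true}$ (0.9
for "high", 0.1 for "low" autocorrelation) and field scale
$\sigma^2_{field} = 0.25$ on a rook-adjacency square lattice (5x5 or
10x10); a standard-normal covariate with effect
$\beta_{true} = (0, 0.5)$; Poisson counts
$O_i \sim \mathrm{Pois}(E_i e^{\eta_i})$ with constant expected counts
$E_i = 50$; response $y_i = \log\{(O_i + 0.5)/(E_i + 0.5)\}$
(continuity-corrected so zero counts remain usable). The contaminated
variant replaces a seeded 20% of responses with draws from a second
Gaussian component shifted by $3\,\mathrm{sd}(y)$, giving a
mixture-with-outliers shape. The generating method for these scenarios
is only loosely specified in the literature; all numeric defaults above
are this package's own choices, fixed once, exposed in `scenario_spec()`
and recorded in the simulation metadata.

What the generator does *not* emulate: irregular administrative
geographies, spatially varying expected counts, covariate-field
confounding, or non-Poisson overdispersion. Tests that pass on these
lattices therefore validate the algorithmic machinery and the
statistical behaviour under the stated conditions, not performance on
any particular real registry dataset.

Two deliberate scoring choices in the recovery study deserve note.
First, the overall level of a CAR field is confounded with the
intercept — only $\beta_0 + \bar\psi$ enters the linear predictor
identifiably — so `parameter_recovery_report()` scores the intercept
against $\beta_0 + \bar\psi_{true}$ (the realised field level is
reported alongside). Second, the claim that the response looks "more
Gaussian" with more areas is checked with a sample-size-honest
statistic, the mean Kolmogorov--Smirnov distance to the moment-fitted
normal, rather than the pass rate of a significance test whose power
itself grows with $n$.

## Numerical choices and degenerate inputs

* EL Newton: convergence when the scaled constraint residuals fall
  below $10^{-12}$ (so the weight-sum identity holds to $10^{-10}$),
  at most 100 iterations, step-halving to keep all $1 + \lambda'f_i$
  positive. Moment columns are rescaled by their maximum absolute value
  before solving.
* A response that is an exact linear fit of the covariates leaves zero
  residual variance; the scale constraint is then unsatisfiable for
  every $\beta$ and initialisation stops with a diagnostic rather than
  fitting a meaningless model.
* Disconnected graphs are allowed for IG and Leroux ($\rho < 1$);
  the intrinsic CAR warns and uses rank $n - c$. Isolated areas warn at
  construction and are rejected by the CAR families.
* Matrices are dense throughout: the intended problem sizes are tens to
  a few hundred areas, where dense eigendecompositions and Cholesky
  factors are faster and simpler than sparse machinery.

## Known limitations

* The EL posterior is much flatter than a parametric one: credible
  intervals for $\beta$ are wide, and far more MCMC iterations are
  needed than for the parametric counterparts.
* In `mele` mode the $\psi$ block targets moments evaluated at the
  initial $\beta$ estimate; this mirrors the reference algorithm but is
  not a coherent joint sampler. Use `psi_moment_beta = "current"` for
  the coherent variant.
* $\rho$ is selected by grid search, not sampled, so its selection
  uncertainty is not propagated.
* WAIC differences between the EL-based spatial priors are intrinsically
  small (all sit near the $2n\log n$ floor); rankings among them should
  be read with that in mind.
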