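---
title: "Benchmarking incidence projection models with incproj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking incidence projection models with incproj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cancer registries publish incidence as an age × period matrix of counts
`Y` with matching person-years `N`: years in rows (ascending), age groups in
columns (ascending, constant width). Public-health planning needs
projections of future counts, with honest uncertainty, often from fairly
short series. `incproj` implements a ladder of projection models of
increasing complexity, produces full predictive distributions of future
counts for each, and scores them against held-out registry years by three
operating characteristics — interval coverage, relative bias, and predictive
precision — so that competing modelling strategies can be compared like for
like.

## The model ladder

All count models act on rates through a log person-years offset:
`E(Y) = N * exp(eta)`.

1. **Constant projections** — the last observed age-specific rates (or raw
   counts) carried forward. Degenerate predictive distribution: a point.
2. **Intercept-only GLM** — `eta = b0`; one rate for everything.
3. **Age–period GLM** — `eta = b0 + b1*age + b2*period + b3*age:period`,
   with age and period as numeric midpoints centered at their training
   means (centering stabilizes the interaction fit; predictions are
   invariant to it).
4. **GAM with an age smoother** — `eta = b0 + b2*period + f(age)` with
   `f` a B-spline; age incidence curves are strongly non-linear, so this is
   the first biologically plausible member.
5. **Bayesian tensor-product smoother ("z-model")** — a smooth age × period
   surface written as a classical random-effects term `eta = b0 + Z z`,
   where `Z` is the row-wise Kronecker product of M-spline marginal bases
   in age and period, `z ~ N(0, tau^-1 I)`, and the precision `tau` has a
   loggamma(1, 0.005) prior.
6. **Bayesian age–period–cohort model (APC)** — Poisson likelihood with
   `eta_ij = mu + alpha_i + beta_j + gamma_k + u_ij`, second-order
   random-walk (rw2) priors on the age, period and cohort effects, an iid
   Gaussian overdispersion effect `u`, and cohort index
   `k = j + M (I - i)` where the grid factor `M` is the ratio of age-group
   width to period width (5 for five-year age groups with yearly data).

GLMs and GAMs default to the negative-binomial family; the Bayesian APC
model is Poisson with explicit overdispersion. Age, period and cohort
effects are linearly confounded (the APC identification problem), so the
package reports them only under sum-to-zero constraints (cohort additionally
detrended) and treats the linear predictor and predictive counts as the
estimands that matter.

## Posterior computation

The Bayesian members are latent Gaussian models: a count likelihood, a
Gaussian field of fixed and structured random effects, and Gamma
("loggamma" on the log scale) priors on precisions. `fit_latent_gaussian()`
samples them with a blocked MCMC scheme:

* **Precisions**: conjugate Gibbs draws,
  `tau_r | z_r ~ Gamma(a + rank(Q_r)/2, b + z_r' Q_r z_r / 2)`, using the
  intrinsic rank (n − 2 for rw2).
* **Latent field**: one-block independence Metropolis–Hastings. At each
  sweep a Gaussian (Laplace) approximation is built at the conditional mode
  (damped Newton with step-halving; uphill-only moves) and the whole field
  is proposed from it. Count likelihoods are log-concave in `eta`, so the
  approximation is excellent and acceptance rates are typically 0.8–0.95;
  the proposal correction makes the chain exact, not approximate.
* **NB dispersion**: random-walk MH on the log dispersion with a vague
  Gamma(1, 0.01) prior, adapted during burn-in and updated after the latent
  field so early misfit is not absorbed into overdispersion. The sampler
  likewise initializes precisions at 1 and seeds the NB mode search from
  the Poisson mode: a tight initial smoothing prior or a collapsed
  dispersion would otherwise pin the field at zero (a classic trap for
  jointly updated scale and field parameters).

Intrinsic rw2 structures make the prior improper along constant and linear
directions; a fixed ridge of 1e-6 on every block keeps the chain proper
without touching the precision updates. Identifiability constraints
(sum-to-zero, cohort detrending) are imposed on reported draws by an exact
projection `x - W (A W)^{-1} A x` whose directions `W` are null vectors of
the design (`B W = 0`), so constraints hold to machine precision while the
linear predictor of every draw is untouched.

The tests compare this engine against long-run gold-standard MCMC (JAGS
with the identical model) on a 5 × 8 fixture — posterior means of the
linear predictor agree within a few hundredths of a posterior SD — and
verify distributional calibration by simulation-based calibration on a
small fully proper model.

## Projection

* Fixed-effect models extrapolate their design (linear period terms extend
  naturally; the age basis is evaluated at the same age groups).
* The tensor model builds its period basis over training years plus the
  requested horizon at fit time, the same device as treating future cells
  as missing responses: coefficients supported only in the future carry
  prior uncertainty, which is what widens the bands.
* The APC model extends the period and cohort random walks with the rw2
  predictive (`x_new ~ N(2 x_prev - x_prev2, tau^-1)`, sequentially) and
  draws fresh overdispersion effects for future cells.
* Maximum-likelihood fits use the plug-in predictive at the MLE
  (negative-binomial or Poisson quantiles at the fitted mean) — no
  parameter uncertainty, deliberately simple and so documented in the
  result.

Equal-tailed 95% intervals follow the discrete convention: `lo` is the
smallest count whose predictive CDF reaches 0.025, `hi` the smallest
reaching 0.975 (sample quantiles of that type when draws are used, 1500–2000
draws by default).

## The rolling hold-out design and the metrics

With target year `T` (the most recent observed), horizon `n`, and an
observation window of `L = 15` years, each model trains on
`[T - n - L + 1, T - n]` and is scored on year `T`; default horizons are
2, 5, 10, 15 and 20 years. The window convention (the training window ends
exactly `n` years before `T`, inclusive) is fixed and documented because
"the 15 years prior" is ambiguous by one year in ordinary speech.

Per age group the package computes:

* **coverage** — indicator of the observed count lying inside the 95% band,
  bounds inclusive; degenerate intervals cover only exact equality;
* **bias** — 0 when observed equals predicted, else
  `100 * (observed - predicted) / observed`, negative = overestimation;
  cells with observed 0 but a nonzero prediction are undefined: they are
  excluded from aggregation and reported in an explicit undefined-count
  rather than assigned an invented penalty;
* **precision** — the predictive standard deviation.

Metrics are averaged arithmetically over age groups into one record per
model × horizon (× any metadata strata). Stored records are never
truncated; clipping extreme bias values (e.g. at −200) is for plots only.
Because "transformed" precision summaries appear in the literature without
a stated transformation, records carry both the raw mean SD and
`log10(1 + mean SD)`, labelled as such.

`pit()` adds the nonrandomized probability integral transform for count
forecasts, `(F(y) + F(y-1))/2`, binned into 10 equal bins: flat for a
calibrated forecast, U-shaped when the predictive is underdispersed.

## The synthetic registry generator

`simulate_registry()` draws tables from a known APC structure:
`eta = base + f_age + drift * period + gamma_cohort (+ interaction)`, with
Poisson or negative-binomial noise and smoothly growing populations. The
cohort curve is twice-integrated noise indexed by `k = j + M (I - i)`, so
the generative geometry matches the Bayesian APC model exactly and
self-consistency tests are meaningful. Defaults emulate a mid-size registry
extract: 40 years, thirteen 5-year age groups covering ages 20–84, about
4 × 10^5 person-years per cell, a log-quadratic age curve spanning roughly
2–90 cases per 100 000, 1% annual drift, and a cohort effect of 0.15 SD on
the log scale. `scenario_library()` spans the ladder — flat, age-only,
age+drift, age × period interaction, full APC, overdispersed — so that each
model is the true model for at least one scenario.

What the generator does *not* emulate: registration delay and
under-reporting, coding changes, migration, population forecast error
(evaluation uses observed future person-years, as backtesting designs do),
and heaped or missing ages. Passing tests on synthetic data therefore
demonstrate internal correctness and calibration of the machinery, not
performance on any particular real registry.

## A note on intercept-only models and overdispersion

A finding worth knowing before quoting coverage numbers: an intercept-only
*negative-binomial* model on data with a strong age gradient absorbs the
entire gradient into its dispersion estimate (fitted dispersion well below
1) and its predictive intervals balloon until they cover almost everything
— near-nominal coverage at useless precision. The textbook failure of
ignoring age (badly undercovering, overconfident intervals) appears in the
*Poisson* intercept-only model, which the model library exposes separately
(`glm_intercept_poisson`). Benchmarks that report very low intercept-only
coverage are implicitly operating at or near the Poisson limit of the
dispersion; comparisons in this package's own tests use the Poisson variant
for that reason, and the vignette flags the NB variant's behavior instead
of silently matching one or the other.

Relatedly, predictive spread grows with the horizon for the structured
Bayesian models (random-walk extrapolation) and for extrapolating fixed
effects under parameter uncertainty, but *not* for intercept-only models,
whose predicted mean (and hence plug-in SD) tracks the pooled training rate
of an earlier window. Monotone-precision checks therefore exclude the
intercept-only member.

## Numerical choices and problem sizes

* Knots: quantile-placed interior knots, clamped boundary knots of
  multiplicity degree + 1. Default marginal dimensions
  `min(10, ceil(I/2)+2)` (age) and `min(8, ceil(J/2)+2)` (period) — chosen
  once for smoothness comparable to standard GAM defaults at registry grid
  sizes; both are arguments.
* MCMC defaults: 2000 sweeps, 500 burn-in. The package's own benchmark
  runs use 1000–1500-sweep chains on grids up to 13 age groups × 15 years
  (the acceptance checks use a 5 × 8 engine fixture, 100 replicate 5 × 10
  calibration registries, and 200 simulation-based-calibration replicates)
  — sizes at which a full ladder comparison completes on a laptop-class
  single core in minutes while leaving Monte-Carlo error well inside the
  tolerances being tested.
* Degenerate inputs: rw2 needs at least 3 levels; a single age column is
  rejected by the smoother; empty age filters, mixed age-group widths, and
  non-positive populations fail fast with the offending cell named.
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; evaluation derives per-(model, horizon) seeds from the master
  seed, so full runs are reproducible byte for byte.

## Known limitations

* The ML projection path ignores parameter uncertainty (plug-in); its
  intervals are anti-conservative for short series. The Bayesian engines
  are the primary path.
* The tensor model's predictive spread beyond the training span comes from
  prior shrinkage of future-supported coefficients, which is sensible but
  prior-dependent; very long extrapolations (beyond ~half the training
  span) lean heavily on the loggamma prior. Because those coefficients
  enter through `exp()`, its predictive counts are heavy-tailed and the
  *mean* predictive SD at long horizons is tail-dominated — enormous in raw
  terms and not stably ordered between adjacent horizons (one reason the
  `log10(1 + x)` companion scale exists). Median-based summaries of its
  draws are far better behaved.
* Hyperpriors for the APC model's four precisions default to
  loggamma(1, 0.005) uniformly; sensitivity to that choice is not explored
  automatically.
* No CRPS, no model averaging, no spatial effects, no demographic
  projection of future populations.
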