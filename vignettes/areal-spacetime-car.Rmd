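---
title: "Modelling areal space-time panels with CAR priors"
author: "carpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling areal space-time panels with CAR priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

carpanel fits Bayesian hierarchical models to *areal panel data*: a
response observed once per areal unit (district, grid cell) and year, with
real-valued covariates attached to each cell. The motivating setting is
district-level crop yield — a yield rate $E_{dt} = Y_{dt}/Z_{dt}$ (production
over harvested area, tons per acre) for $d = 1,\dots,D$ districts and
$t = 1,\dots,T$ years, regressed on climate covariates (maximum temperature,
rainfall, humidity, wind speed, sunshine). Such data are spatially and
temporally dependent: neighbouring districts share soil and weather, and a
district's conditions persist between years. Ignoring that dependence
biases the apparent precision of covariate effects; modelling it separates
climate signal from structured regional and annual variation.

## The model

All families share the Gaussian observation layer

$$E_{dt} \sim N(\mu_{dt},\, \nu^2), \qquad
  \mu_{dt} = x_{dt}'\beta + \psi_{dt},$$

with a homoscedastic observation ("nugget") variance $\nu^2$ and a
structured spatio-temporal effect $\psi_{dt}$ whose form defines the
family:

* **independent_glm** — $\psi_{dt} = 0$; the independent-error baseline.
* **st_anova** — $\psi_{dt} = \phi_d + \delta_t\ (+\ \gamma_{dt})$: a
  spatial main effect, a temporal main effect, and an optional iid
  interaction $\gamma_{dt} \sim N(0, \tau^2_I)$ (off by default).
* **st_linear** — $\psi_{dt} = \phi_d + (\alpha + \delta_d)\,
  \frac{t - \bar t}{T}$ with $\bar t = (T+1)/2$ on the index scale:
  CAR-distributed area intercepts and area slopes around an overall linear
  trend $\alpha$.
* **st_ar** — $\psi_{dt} = \phi_{dt}$, a first-order autoregressive chain
  of spatial fields: $\phi_{\cdot 1} \sim N(0, \tau^2_T Q(\rho_S)^{-1})$
  and $\phi_{\cdot t} \mid \phi_{\cdot, t-1} \sim
  N(\rho_T\, \phi_{\cdot, t-1},\ \tau^2_T Q(\rho_S)^{-1})$.

Spatial effects use the Leroux conditional autoregressive (CAR) prior: on
a lattice with 0/1 adjacency $W$ and neighbour counts $D_w$, the
unit-scale precision is

$$Q(\rho) = \rho\,(D_w - W) + (1-\rho)\, I, \qquad \rho \in [0, 1),$$

and the field has covariance $\tau^2 Q(\rho)^{-1}$. This interpolates
between independence ($\rho = 0$, $Q = I$) and the intrinsic CAR limit
($\rho \to 1$). Temporal main effects $\delta_t$ use the same form on the
path graph $1 - 2 - \cdots - T$, which gives a proper prior whenever
$\rho_T < 1$. We chose the Leroux parameterisation because it is the
standard proper-CAR family for spatio-temporal areal modelling and nests
both limiting behaviours with a single interpretable parameter per block;
intrinsic ($\rho = 1$) inference is deliberately out of scope.

### Priors and defaults

* $\beta_j \sim N(0, 10^5)$ independently (effectively vague on the scale
  of yield-rate regressions); the same prior applies to the st_linear
  overall slope $\alpha$.
* Every variance ($\nu^2$, $\tau^2_S$, $\tau^2_T$, $\tau^2_{int}$,
  $\tau^2_{slo}$, $\tau^2_I$) has an InverseGamma(shape = 1,
  scale = 0.01) prior.
* Every dependence parameter $\rho$ has a Uniform(0, 1) prior.

All three are adjustable through `st_prior()` and the pipeline config
file. The inverse-gamma default has infinite prior mean; it is weak on
variance scales above $\sim 0.01$ and is the conventional default in this
model class.

### Covariate transforms

`default_transforms()` encodes the standard scale adjustments for this
kind of yield analysis — temperature enters as $\sqrt{\text{temperature}}$
and rainfall as $\log(\text{rainfall})$; other covariates enter
untransformed. Transforms are validated against their domains record by
record, and covariates are used on their transformed, *un-standardised*
scale so that reported coefficients are directly interpretable.

## Inference

`run_mcmc()` is a Gibbs sampler with Metropolis steps for the dependence
parameters. Per sweep:

1. $\beta$ — exact draw from its Gaussian full conditional
   (precision $X'X/\nu^2 + I/\sigma^2_\beta$).
2. Each random-effect block — exact draw from its Gaussian full
   conditional (likelihood term plus CAR/iid prior term). The st_ar chain
   is updated slice by slice in time.
3. Each variance — conjugate draw from
   $\text{IG}(a + k/2,\ b + q/2)$ where $q$ is the block's quadratic form
   ($u'Q(\rho)u$ for CAR blocks, the residual sum of squares for $\nu^2$).
4. Each $\rho$ — reflected Gaussian random-walk Metropolis on $(0,1)$.
   The acceptance ratio includes the $\tfrac12 \log\det Q(\rho)$ term,
   computed in $O(n)$ from the once-per-lattice eigenvalues of $D_w - W$:
   $\log\det Q(\rho) = \sum_i \log(\rho\lambda_i + 1 - \rho)$. The
   proposal scale adapts every `adapt_interval` sweeps during burn-in
   toward a 40–50% acceptance rate and is frozen afterwards, preserving
   the correct stationary distribution post burn-in.

**Identifiability.** An intercept plus sum-free CAR blocks are only
jointly identified, so after each block draw the block mean is removed and
absorbed into the intercept (or into $\alpha$ for the st_linear slope
block). The transfer leaves the linear predictor unchanged — a property
the test suite asserts to $10^{-10}$ — and is the standard soft
alternative to hard sum-to-zero constraints. The non-centred kernel (no
re-centring) is retained internally for distributional validation of the
sweep.

**Protocol.** The reference configuration is 20,000 burn-in sweeps,
100,000 kept sweeps, thinning 10 (10,000 stored draws), single chain.
Stored draws are the thinned post-burn-in states of all scalar parameters,
effect blocks and the linear predictor. Everything is reproducible from
the single integer seed. Tests and the acceptance script use scaled
configurations (hundreds to a few thousand sweeps) chosen so that
Monte-Carlo error is small relative to the tolerances they assert; the
vignette's examples use the same scale.

## Model choice and validation

For stored draws $\theta_1,\dots,\theta_S$ with pointwise densities
$f(y_i \mid \theta_s)$:

* **DIC** $= \bar D + p_D$, $\bar D = \text{mean}_s\,(-2\log L(\theta_s))$,
  $p_D = \bar D - D(\hat\theta)$. The plug-in $\hat\theta$ uses the
  posterior means of the parameters entering the likelihood — the linear
  predictor (which is linear in coefficients and effects, so its plug-in
  equals the mean of the per-draw predictors) and $\nu^2$. $p_D$ is
  parameterisation-dependent; this convention is stated because others
  exist.
* **WAIC** $= -2(\text{lppd} - p_W)$ with
  $\text{lppd} = \sum_i \log \text{mean}_s f(y_i\mid\theta_s)$ and
  $p_W = \sum_i \text{var}_s \log f(y_i\mid\theta_s)$ (sample variance,
  denominator $S-1$).
* **LMPL** $= \sum_i \log \text{CPO}_i$, with the harmonic-mean estimator
  $\text{CPO}_i = [\text{mean}_s f(y_i\mid\theta_s)^{-1}]^{-1}$.
  Densities are floored at the smallest positive normal double and
  affected observations are flagged on the result.
* **Validation**: residuals against the posterior-mean fit give RMSE and
  MAE; the per-observation predictive distribution is approximated as
  Gaussian with mean $\text{mean}_s \mu_{is}$ and variance
  $\text{var}_s \mu_{is} + \text{mean}_s \nu^2_s$, from which the
  closed-form Gaussian CRPS and the 95% interval coverage (`cvg`, in
  percent) follow.

All validation statistics are **in-sample** on the full panel: the
workflow this package mirrors reports whole-panel fit quality, and no
hold-out split is part of the reference protocol. For a well-specified
model, in-sample `cvg` should sit near the nominal 95 — the simulation
tests assert it lands in [93, 97] on the default synthetic design.
`compare_models()` assembles one row per fit and flags the best model per
criterion (minimum for DIC/WAIC/RMSE/MAE/CRPS, maximum for LMPL and
log-likelihood, closest to 95 for coverage; ties share the flag).

Residual aggregations mirror the two standard displays: per-area mean and
SD of residuals over years (a map-ready table for spotting leftover
spatial pattern), and per-year observed and fitted means over areas with a
pointwise credible band from the draws of the area-averaged fit.

## The synthetic-data generator

`simulate_covariates()` emulates the *statistical shape* of district-level
climate data: each covariate is a smooth spatial base field (a CAR draw,
$\rho = 0.75$), plus a common yearly shift, plus cell noise, clamped into
plausible physical ranges (temperature 20–35 °C, rainfall positive and
log-normal-like around $e^{7.2}$ mm, humidity 60–90%, wind speed
0.5–3 m/s, sunshine 4–9 h). The clamps guarantee the sqrt/log transforms
are defined for every seed. `simulate_panel()` then draws the structured
effects from the chosen family's prior and adds Gaussian noise, returning
the raw-scale panel and a complete truth record.

The default truth places coefficients and variance parameters at the scale
of a district-level yield-rate analysis ($\nu^2 = 3.4$,
$\tau^2_S = 0.2$, $\tau^2_T = 0.4$, $\rho_S = 0.45$, $\rho_T = 0.25$,
temperature coefficient 4.8 on the sqrt scale, wind-speed coefficient
exactly 0). These are fixture choices for realistic simulation studies,
not estimates of any real dataset. The default study scenario is an
8 × 8 rook grid over 17 years — 1088 cells, matching the motivating
design's size; the true district contiguity graph is not public, so a grid
stands in, and any edge-list lattice can be substituted.

What the generator does **not** emulate: the real covariates' marginal
distributions and cross-correlations, station-to-district assignment
artefacts, reporting changes over years, or non-Gaussian response
features. Passing recovery tests therefore demonstrates correctness of the
inference machinery under the model's own assumptions — not that the model
is right for any particular real panel.

## Numerical and design choices

* **Canonical order.** Records are stored year-major, areas ascending
  within each year; flattened vectors index cell $(d, t)$ at row
  $(t-1)D + d$ (1-based, matching R). A single stated convention prevents
  silent misalignment between effect vectors and observations; the design
  matrix is invariant to input record order.
* **Dense algebra.** At $D \le 64$ areas, dense Cholesky factorisations
  (at most $64 \times 64$ per block per sweep) are faster than sparse
  machinery; log-determinants over $\rho$ reuse cached eigenvalues.
* **Quantiles.** Linear interpolation between order statistics (R type 7)
  everywhere.
* **Degenerate inputs.** $T = 1$ gives an edge-free path graph (iid
  temporal prior); $\rho$ proposals are reflected into $(0,1)$ and clipped
  away from the endpoints by $10^{-12}$; `rho = 1` is allowed only for
  inspecting the intrinsic precision structure, never for densities.
* **Homoscedastic $\nu^2$.** A single observation variance per model, the
  parameterisation under which one nugget variance is reported per fitted
  model; heteroscedastic noise is out of scope.
* **st_ar without a separate temporal main effect.** The AR family models
  all temporal structure through the chain itself; adding a free
  $\delta_t$ on top would duplicate the chain's role and bring back the
  identifiability problems the centring handles, so it is omitted.
* **Interaction off by default.** The iid $\gamma_{dt}$ in st_anova is
  flag-gated: with one observation per cell it competes directly with the
  nugget and is only weakly identified.
* **Significance.** A coefficient is read as influential when its
  equal-tailed 95% credible interval excludes zero — the interval logic
  under which, in the default synthetic truth, the null wind-speed
  coefficient is expected to be flagged non-influential.
* **Single chain.** The reference protocol is single-chain; acceptance
  rates and the `ess()` diagnostic are exported, and independent seeds
  give independent chains for users who want convergence comparisons.

## Problem sizes used in the test suite

The dense-Gaussian full-conditional oracles run on instances with
$D\cdot T \le 12$, where exact conditioning of the joint Gaussian is
cheap and the comparison tolerance is $10^{-8}$. The simulation studies
use the full 8 × 8 × 17 design (ten replicates, 2,000 burn-in + 8,000
kept sweeps thinned by 4) for coefficient recovery, coverage and the
significance logic, and ten 5 × 5 × 10 panels for DIC discrimination
against the independent-error baseline. These sizes give Monte-Carlo
error comfortably inside the asserted bands while keeping a full test run
in a few minutes — they are the package's chosen verification design.

## Known limitations

* Gaussian responses only; no Binomial/Poisson families, offsets beyond
  the exposure-derived response, or spatially varying coefficients.
* AR order 1 only; no multivariate CAR; no intrinsic-CAR inference.
* Missing response cells are a hard validation error: the methods assume a
  complete rectangular panel and no imputation is attempted.
* The harmonic-mean CPO estimator is known to be unstable when single
  observations are highly influential; the density floor flags, but does
  not repair, such cases.
* In-sample validation statistics are optimistic relative to hold-out
  assessment; blocked cross-validation is a natural extension but not part
  of the reference workflow.

## A minimal session

```{r}
library(carpanel)

lat <- grid_lattice(5, 5)
mod <- st_model("st_anova",
                covariates = c("temperature", "rainfall", "humidity",
                               "windspeed", "sunshine"))
sim <- simulate_panel(mod, default_truth("st_anova"), lat, 10, seed = 3)
panel <- apply_transforms(sim$panel, default_transforms())

fit <- run_mcmc(panel, lat, mod, st_prior(),
                mcmc_config(n_burn = 500, n_keep = 2000, thin = 4,
                            seed = 7))
summary(fit)
criteria_bundle(fit)
aggregate_fitted_temporal(fit)
```

The file-based pipeline wraps the same steps:
`pipeline_simulate()` writes `panel.csv` / `adjacency.txt` / `truth.json`,
`pipeline_fit()` fits one family and writes summary, criteria, draws and a
run log (package version, seed, config hash, input hashes), and
`pipeline_compare()` fits all four families and writes the comparison and
aggregation tables. `inst/cli/carpanel.R` exposes the three commands to a
shell.
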