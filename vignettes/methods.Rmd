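---
title: "Methods: model-based geostatistics for under-five proportion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based geostatistics for under-five proportion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5map)
```

## The model

`u5map` maps the proportion of a population under five years of age from
geolocated household-survey clusters. The observed cluster proportion at
location $s$ and survey wave $t$ is modelled on the identity (proportion)
scale:

$$ y(s,t) = x(s)'\beta + Z(s,t) + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma_e^2), $$

where $x(s)$ holds an intercept and environmental covariates, and $Z$ is a
zero-mean Gaussian process with separable space–time covariance

$$ \operatorname{Cov}\{Z(s,t), Z(s',t')\}
   = \sigma^2 (\kappa h) K_1(\kappa h)\, \rho^{|t-t'|},
   \qquad h = \lVert s - s' \rVert . $$

The spatial part is the Matérn family at smoothness $\nu = 1$ (the
two-dimensional SPDE default), with nominal range $\sqrt{8}/\kappa$ — the
distance at which correlation falls to roughly 0.1. The temporal part is a
first-order autoregression over integer survey-wave indices. Distances are
Euclidean in decimal degrees; kilometre figures are presentation only, via
the fixed constant 111.32 km/degree (`KM_PER_DEGREE`). The package targets
near-equatorial study areas, where ignoring the latitude dependence of that
conversion distorts distances by under 2%.

Modelling a proportion with a Gaussian likelihood and identity link is an
approximation: it admits predictions outside $[0,1]$. The package clips
predictions (and simulated observations) to $[0,1]$ and reports the number
of clip events rather than hiding them; at the parameter magnitudes of
interest (mean $\approx 0.18$, total sd $\approx 0.05$) clipping is rare.

## Inference

Fitting is maximum marginal likelihood over
$\theta = (\log\sigma^2, \log\kappa, \operatorname{atanh}\rho,
\log\sigma_e^2)$ with the fixed effects profiled out in closed form
(generalized least squares) at every evaluation of the dense $n \times n$
covariance. Gradients are analytic, using
$\partial\{(\kappa h)K_1(\kappa h)\}/\partial\log\kappa
= -(\kappa h)^2 K_0(\kappa h)$, and the optimizer is bounded L-BFGS-B from
up to five dispersed deterministic starts (variance split between field and
nugget from 5/95 to 95/5, range from 1/20 to 1/2 of the domain diameter,
$\rho \in \{-0.3, 0, 0.3, 0.6\}$); the best converged start wins. Cholesky
factorizations carry an escalating diagonal jitter
($10^{-10}$ to $10^{-6}$ of the mean diagonal) before failing with
eigenvalue diagnostics.

Uncertainty is Laplace-style: the covariance of $\hat\theta$ is the inverse
of a numerically differentiated Hessian of the profile negative
log-likelihood, and per-parameter summaries (mean, sd, 5%/50%/95%
quantiles, the conventional posterior-table layout) are obtained by
back-transforming Gaussian quantiles through the monotone transforms, with
delta-method standard deviations. Fixed-effect uncertainty is the exact GLS
covariance $(X'K^{-1}X)^{-1}$. These are approximations to a Bayesian
posterior, not the posterior itself; their empirical calibration is what the
coverage tests check.

Model comparison uses $\mathrm{DIC} = D(\hat\theta) + 2 p_D$ with
$D = -2\,\ell(\hat\theta)$ and the effective number of parameters
$p_D = \operatorname{tr}(S)$, where $S$ is the Gaussian smoother matrix
mapping $y$ to fitted latent values (fixed-effects hat matrix plus the GP
smoother). The log marginal likelihood reported alongside is the
Gaussian-process marginal over the latent field at the optimized
hyperparameters; a hyperparameter-level integrated likelihood is out of
scope.

### An identifiability guard on the range

A Matérn component whose range lies below the inter-point distances the
sampling design actually resolves is statistically indistinguishable from
extra nugget variance: the likelihood surface has a flat ridge connecting
$(\sigma^2\!=\!0,\ \sigma_e^2\!=\!v)$ to
$(\sigma^2\!=\!v,\ \text{range}\!\to\!0)$. The fit therefore bounds the
nominal range below by the 1% quantile of pairwise distances
(`range_floor_q`, configurable). This is the dense-likelihood analogue of
keeping an SPDE range above the mesh resolution, and it is what makes the
field-vs-nugget variance decomposition reported in the summary table
meaningful.

## Prediction

Surfaces are universal kriging: for a cell with covariates $x^*$ at wave
$t^*$,

$$ \mu^* = x^{*\prime}\hat\beta + k^{*\prime} K^{-1}(y - X\hat\beta),
   \qquad
   v^* = \sigma^2 - k^{*\prime}K^{-1}k^*
         + m' (X'K^{-1}X)^{-1} m, $$

with $m = x^* - X'K^{-1}k^*$ the (optional, default on) fixed-effect
uncertainty term. Central credible bounds default to 95%
($\mu^* \pm 1.96\sqrt{v^*}$); the 90% interval that matches the 5%/95%
summary-table style is available through `level = 0.90`. Cells are
processed in tiles (default 4000) so memory stays bounded; nodata cells
propagate. With a zero nugget the predictor interpolates the data exactly —
one of the package's acceptance checks.

## Validation

* **Holdout**: a seed-reproducible simple random split (default 10%;
  optionally stratified by urban/rural), scored by MPE, MAE, RMSE and
  Pearson's $r$. The MPE sign convention is *predicted minus observed*; the
  sign language sometimes attached to such figures in the literature is
  ambiguous, so the convention is stated here once and used everywhere.
* **Leave-one-out CPO**: closed form from the fitted precision,
  $\mathrm{CPO}_i = N(y_i;\ \mu_{-i},\ 1/Q_{ii})$ with $Q = K^{-1}$ and
  $\mu_{-i} = y_i - (Qr)_i / Q_{ii}$. The fixed effects stay at their
  full-data GLS estimate (an empirical-Bayes convention; no per-deletion
  re-estimation and hence no $n/(n-1)$-style variance adjustment). Low-CPO
  observations are flagged below a configurable quantile without declaring
  failure — the screening is qualitative.
* **Residual semivariogram**: empirical semivariance of standardized LOO
  residuals in distance bins, with pointwise min/max envelopes from 99
  seed-controlled permutations of residuals over fixed locations. A
  well-specified fit stays inside the envelopes; genuine residual spatial
  structure breaches the lower envelope at short range.

## The synthetic generator

Because the motivating survey microdata and covariate rasters are
access-restricted, the generator is a first-class module that emulates
their statistical structure on a shared grid:

* four covariate layers (accessibility, EVI, a 0–5 land-cover code,
  right-skewed night-time lights) painted by smooth random-cosine fields,
  continuous layers standardized over the valid-cell mask; a small masked
  fraction imitates water bodies;
* an urban indicator defined as night-time lights above the 90th
  percentile;
* cluster *true* locations sampled over valid cells, stratified urban/rural
  (default 30% urban, emulating urban oversampling relative to urban land
  area); the observed proportion is the linear predictor at the true
  location plus an exact Matérn–AR(1) draw (dense Cholesky) plus Gaussian
  nugget noise, clipped with a logged count;
* *recorded* coordinates are randomly displaced — up to 2 km (urban), 5 km
  (rural), 10 km for 1% of rural clusters — reproducing the anonymisation
  error real cluster data carry. Covariates for fitting are extracted at
  the displaced location (point lookup, or a buffer average with the modal
  land-cover class); the generator/fitting asymmetry is deliberate.
* household counts uniform in (20, 50); persons Poisson around 5 per
  household; `n_under5` back-filled as `round(p * n_people)`, so printed
  counts match the continuous proportion only up to rounding;
* admin zones as a Voronoi raster; population as a log-normal surface
  attracted to night-time lights and scaled to a national total.

The generator's defaults are the study-scale conditions: intercept 0.1815,
covariate effects of a few parts per thousand per standard deviation,
marginal variance $7\times10^{-4}$, nugget $2.2\times10^{-3}$, nominal
range $\sqrt{8}/e^{-0.47} \approx 4.5^\circ$, $\rho = -0.47$, 1624 clusters
over 3 waves. What the generator does *not* emulate — and what passing
tests on it therefore cannot establish about real data — includes: survey
weights and the full two-stage PPS design, non-Gaussian (binomial)
observation error, covariate measurement error beyond geomasking,
non-stationarity, and real landscapes' covariate collinearity structure.

## Numerical and design choices

* Survey waves are integer indices $0, 1, \dots$; when several surveys
  share a calendar year a single index can be assigned to them (the
  time mapping is the caller's choice; the generator spreads clusters
  evenly over waves).
* Land cover enters the design matrix as one numeric code column — matching
  the single "land cover" coefficient convention — rather than as dummies.
* Best-subset selection enumerates all $2^p$ Gaussian regressions
  ($p \le 20$ guarded) and scores
  $\mathrm{BIC} = -2\hat\ell + k\log n$ with $k$ counting intercept,
  slopes and the error variance; ties break toward fewer covariates, then
  lexicographic labels. Exhaustive enumeration finds the same optimum as a
  branch-and-bound search and is trivially auditable.
* The comparison menu derived from a selected set of $p$ covariates is the
  full set plus all $p$ leave-one-out subsets ($p = 4$ gives the
  conventional five-model table).
* Zone credible bounds are sums of cellwise bounds — conservative
  envelopes, not joint posterior quantiles, since surfaces do not retain
  cell-level posterior correlation; posterior-sampling aggregation would be
  the extension.
* All randomness flows from explicit seeds; the pipeline derives stage
  seeds as `(seed mod 1e6) * 1000 + stage`, so stages rerun in isolation
  reproducibly and a rerun of the same configuration is bit-identical.

## Problem sizes used by the test harnesses

The test suite exercises the estimator at deliberately chosen scales: exact
oracle comparisons at $n \le 30$; the σ²=0 noise-recovery harness at
$n = 250$ with 10 replicates; study-scale parameter recovery at $n = 800$
clusters over 3 waves with 20 replicates (range, intercept coverage and
nugget checks); interval calibration over 5 independent fields × 100
held-out cells (500 fresh sites) in a well-identified regime (range
$1^\circ$ on a $10^\circ$ domain, field and nugget variances both
$1.5\times10^{-3}$, 300 clusters per field) — sized so the binomial error
of an empirical coverage estimate is small relative to the acceptance band;
and the end-to-end demo on a 50×50 grid with 300 clusters. The
`scripts/acceptance.R` run uses the full 1624-cluster study scale.

## Known limitations

* Dense-likelihood cost is $O(n^3)$; the intended regime is
  $n \lesssim 4000$ observations. A sparse (GMRF) backend would be the
  natural extension, with this implementation as its reference oracle.
* The Gaussian identity-link likelihood ignores the binomial denominator
  information in `n_under5 / n_people`.
* Laplace quantiles are symmetric on the transformed scale; strongly
  skewed likelihood surfaces (small $n$, weak identification) are
  summarized only approximately, and $\rho$ in particular is weakly
  identified with few waves.
* Credible intervals are conditional on the estimated covariance
  parameters (plug-in kriging); the fixed-effect term is included but
  hyperparameter uncertainty is not propagated into prediction intervals.
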