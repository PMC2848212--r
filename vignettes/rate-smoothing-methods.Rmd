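---
title: "Smoothing small-area hospitalization rates with multiple-membership multilevel models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing small-area hospitalization rates with multiple-membership multilevel models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hospitalization (or mortality) rates mapped at the municipal level are
unstable: most municipalities are small, so a handful of admissions moves a
rate across the whole color scale of a choropleth. A raw risk-adjusted rate
treats each area as an island; the estimate that is optimal for one area in
isolation is a poor basis for reading geographic structure off a map.
`mmsmooth` implements the classical remedy — empirical-Bayes smoothing
through a hierarchical Poisson model — in the *multiple membership* flavor:
each municipality is simultaneously a member, with weights, of the
neighborhoods of every municipality within a distance radius, and
optionally of one administrative or environmental grouping.

## Model

Let $O_i$ and $E_i$ be the observed and expected admissions of municipality
$i$ ($E_i$ from indirect standardization, below). Counts are modeled as
$O_i \sim \text{Poisson}(\mu_i)$ with

$$\log \mu_i = \log E_i + \alpha + x_i\beta + u_i + \sum_{j \in \partial_i} z_{ij} v^*_j + w_{k(i)}$$

* $u_i \sim N(0, \sigma^2_u)$ is unstructured **heterogeneity**: extra-Poisson
  variation with no spatial pattern, shrinking areas toward the regional mean.
* $\partial_i$ is the set of municipalities whose centroid lies within
  `radius_km` (default 25 km) of $i$'s centroid, *including $i$ itself*;
  $z_{ij} = 1/|\partial_i|$, so each row of the weight matrix $Z$ sums to
  one. $v^*_j \sim N(0, \sigma^2_v)$ is the latent effect municipality $j$
  contributes to its neighbors; the realized **clustering** (spatial) effect
  of area $i$ is the weighted mean $v_i = [Z v^*]_i$, shrinking areas toward
  their neighborhood mean.
* $w_k \sim N(0, \sigma^2_w)$ is an optional third random effect: the health
  district (ASL) in **Model B**, the environmental-risk area in **Model C**;
  **Model A** omits it. All cross-covariances between $u$, $v^*$ and $w$ are
  fixed at zero — the identifiable specification that also sidesteps the
  negative-variance pathologies of unconstrained covariance estimation.
* $x_i\beta$ is an optional area-level fixed effect (none by default).

Self-inclusion in $\partial_i$ is a deliberate choice: the neighborhood of
an isolated area is then itself, every row of $Z$ is non-empty, and the
model degrades gracefully to pure heterogeneity. A flag on
`build_neighborhoods()` excludes the index area for sensitivity analysis.
The weights are row-normalized ($1/|\partial_i|$): this is the only reading
under which each area's weights sum to one.

For Model C, municipalities outside every risk area form their own
thirteenth group rather than being dropped: with 258 areas and 12 exclusive
risk zones this yields a mean group size of $258/13 = 19.85$, which is how
the regional summaries we replay were evidently computed. For the same
reason `summarize_membership()` computes the mean group size $\bar m$ as
the quotient (areas / groups) by default — with six districts over 258
municipalities this gives exactly 43.00, whereas an area-weighted mean
would not — and the area-weighted convention remains available as an
option.

### Variance decomposition

The total random variance *for a municipality* is
$\sigma^2_u + \sigma^2_v/\bar n \,(+\, \sigma^2_w/\bar m)$, where $\bar n$
is the mean neighborhood size: the clustering variance enters per area
diluted by averaging over the neighborhood. The share
$(\sigma^2_v/\bar n) / \text{total}$ is the **spatially structured
variability quota**. `decompose_variance()` has two rounding modes:
`"none"` (full precision, for real analyses) and `"paper_4dp"`, which
rounds each per-area quotient to 4 decimals before summing — the
convention under which published tables of this arithmetic reproduce to
the printed digit. On realistic magnitudes the two differ by well under
half a percentage point.

### Risk adjustment and the rates

Expected cases come from a region-wide logistic model on sex and eight age
classes (0, 1–4, 5–14, 15–24, 25–44, 45–64, 65–74, >74), fitted on grouped
binomial data (coefficients identical to an individual-record fit):
$E_i = \sum_s \text{pop}_{is}\,\hat p_s$. Because the model has an
intercept and is evaluated on its training data, $\sum_i E_i = \sum_i O_i$.
Fit quality is summarized by the concordance (c-)statistic, computed
exactly from the grouped cells with ties weighted one half. If the 16
cells separate, 0.5 cases and 0.5 non-cases are added to every cell (a
logged continuity correction).

The **risk-adjusted rate** is the indirectly standardized
$\text{RAR}_i = (O_i/E_i) \times \text{crude regional rate}$, and the
**smoothed** rate replaces the raw ratio with the model's fitted relative
risk: $\text{SRAR}_i = \exp(\hat\alpha + x_i\hat\beta + \hat u_i + [Z\hat
v^*]_i + \hat w_{k(i)}) \times \text{crude}$. The fitted intercept is kept
inside the SRAR by default (it is part of the fitted risk surface); a
`recenter` flag divides it out, pinning the regional level at exactly the
crude rate. Reported crude rates are truncated (not rounded) at the
reporting precision, the convention under which printed regional rates
reproduce exactly from their case and population totals; full precision is
available with `digits = NULL`.

## Estimation

`fit_poisson_mmm()` maximizes the Laplace-approximated marginal likelihood.
The combined random-effect design $T = [I \mid Z \mid A]$ (identity for
$u$, the weight matrix for $v^*$, a group indicator for $w$) is sparse; for
fixed $(\alpha, \beta, \log\sigma^2)$ an inner damped-Newton loop finds the
joint conditional mode $\hat b$ of all random effects (sparse Cholesky of
$T'WT + P$, step-halving on the penalized objective), and the outer
optimizer (`nlminb`) moves the parameters against

$$\ell \approx \log f(y \mid \hat b) - \tfrac12 \hat b' P \hat b +
\tfrac12 \log\det P - \tfrac12 \log\det(T'WT + P).$$

Numerical choices, all overridable through `mmm_control()`:

* variances are optimized on the log scale with a floor of $10^{-8}$;
* an estimate stuck at the floor is fixed at exactly zero and the model
  refit without that component — for the clustering variance this mirrors
  the classical treatment of negative variance estimates and raises the
  `clustering_variance_floored` flag; a floored component is not counted
  in $k$, so the AIC ($2k - 2\ln L$) penalizes only estimated parameters;
* initialization is deterministic: $\alpha$ from the null Poisson fit
  ($\log \sum O / \sum E$), every variance at 0.1; convergence at relative
  log-likelihood change $10^{-10}$ (inner gradient tolerance $10^{-9}$),
  so refitting reproduces estimates to machine-level accuracy;
* standard errors come from the numerically differentiated observed
  information in $(\alpha, \log\sigma^2)$, mapped to the variance scale by
  the delta method; SEs are reported absent when the information matrix is
  not positive definite (typically at a boundary);
* Wald p-values for variances are **two-sided** by default. The choice is
  empirical: on tabulated estimate/SE pairs from published analyses of
  this model the printed p-values match $2(1-\Phi(\hat\sigma^2/SE))$ and
  not the one-sided version; `wald_variance_pvalue()` offers both.
* AIC ties (identical AIC, different $k$) rank the smaller model first.

Model comparison refuses fits on different data. Adding the third level
can only raise the maximized log-likelihood (the models are nested at
$\sigma^2_w = 0$), which holds in the implementation up to optimizer
tolerance and is tested.

## The synthetic-data generator

No admission-level data can ship with the package, so every end-to-end
property is exercised on synthetic area tables that emulate the structure
the models assume, via `synthetic_config()` / `simulate_area_table()`:

* **258 municipalities** in a 200 × 150 km rectangle (the scale of an
  elongated southern-European region), centroids uniform;
* **log-uniform populations** between 500 and 100,000 — reproducing the
  strong skew of real municipal populations, which is what makes smoothing
  matter: most areas are small, a few are cities;
* **6 health districts** built by nearest-seed (Voronoi-like) partition, so
  districts are spatially contiguous as real ones are — this is what makes
  a district effect distinguishable from generic spatial clustering;
* **12 mutually exclusive risk areas** of 10 km radius centred on randomly
  chosen municipalities (areas outside all of them form the "none" group);
* **baseline admission probabilities** per sex × age cell: age-increasing,
  male-skewed, with a population-weighted crude rate of ≈25 per 10,000 —
  the scale of chronic respiratory disease admissions. Published analyses
  of this model class do not report their baseline risks, so these
  defaults are a plausibility choice, fixed once here;
* counts are drawn **Poisson at stratum level** with mean
  $\text{pop}_{is} \cdot \text{risk}_s \cdot \exp(u_i + [Zv^*]_i + w_{k(i)})$,
  matching the analysis model's distributional assumption (per-person
  rates above 0.95 are truncated with a warning);
* the generating `truth` (realized effects, true relative risks, expected
  counts) is returned and can be written as a sidecar CSV for recovery
  tests;
* fixing `seed` fixes every output byte.

What the generator deliberately does **not** emulate: real administrative
polygon geometries and shared-border adjacency (surface areas and map
polygons come from a Voronoi tessellation of the centroids, implemented in
the package by half-plane clipping), migration and temporal dynamics, and
area-level covariates such as deprivation. Tests passing on these tables
therefore validate the statistical machinery under the model's own
assumptions, not the fidelity of any particular real-world geography.

## Validation design

The test suite pins the arithmetic to published worked examples (variance
decomposition quotas, crude regional rates) and validates the estimation
machinery at three levels, with problem sizes chosen to keep the full suite
in the minutes range:

* **MCMC oracle** — on three instances of 12–15 areas the Laplace point
  estimates of $(\alpha, \sigma^2_u, \sigma^2_v[, \sigma^2_w])$ are checked
  against the 95% credible intervals of a JAGS fit of the identical
  likelihood (vague uniform priors on the random-effect SDs). The
  instances use strong variance signals ($\sigma^2_v = 2$, informative
  counts) so the ML estimates are interior: at boundary estimates
  ($\hat\sigma^2 = 0$, common and legitimate at such sizes) the interval
  comparison is vacuous, since a positive-support posterior never covers 0.
* **Parameter recovery** — 50 replicates of 200 areas at
  $(\sigma^2_u, \sigma^2_v) = (0.05, 0.7)$, radius 25 km on 200 × 150 km:
  the median relative bias of each variance estimate must stay below 25%.
  With a genuine district effect ($\sigma^2_w = 0.05$, 6 contiguous
  districts; 20 replicates) Model B must beat Model A on AIC in the
  majority of replicates.
* **Smoothing behavior** — across 20 replicates of 100 areas, the absolute
  smoothing correction $|RAR - SRAR|$ must be negatively rank-correlated
  with population size in at least 90% of replicates, and the SRAR must be
  closer to the generating truth than the RAR on average — the premise of
  smoothing, checked rather than assumed.

## Known limitations

* The Laplace approximation is least accurate for very small counts; the
  MCMC oracle bounds the error at desk scale but a fully Bayesian fit
  (e.g. BYM-type CAR models) is the reference for production inference on
  sparse diseases.
* Neighborhoods are distance-radius balls on centroids; shared-border
  adjacency and distance-decay weights are out of scope.
* The risk-adjustment model uses sex and age main effects only (no
  interactions, no deprivation or exposure covariates).
* SRAR uncertainty intervals are not produced; the smoothing is
  empirical-Bayes with plugged-in variance components.
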