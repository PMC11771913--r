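---
title: "Crash hotspots and spatially dependent injury severity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crash hotspots and spatially dependent injury severity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crashspot)
```

## The problem

Older drivers (conventionally, age 65 and above) are among the
highest-risk road users, and the severity of the crashes they are involved
in has a spatial dimension: crashes concentrate along particular corridors
and intersections, and nearby crashes share unobserved environmental
conditions. `crashspot` implements a two-stage analysis of point-referenced
crash records:

1. **Hotspot identification.** Density-based clustering (DBSCAN) over the
   planar crash coordinates finds high-density crash locations, explored
   over a grid of radius and density-threshold values and exported as
   convex-hull polygons.
2. **Severity modelling.** A Bayesian *spatial lag binary probit* relates
   the binarised injury outcome (property-damage-only versus injury or
   fatality) to coded crash covariates while letting each crash's latent
   injury propensity depend on its neighbours', and is compared against a
   non-spatial probit by the deviance information criterion (DIC).

Because crash registries are rarely redistributable, the package carries a
first-class synthetic-data module that generates both stages' inputs from
known ground truth, so every claim the package makes is testable end to end.

## Stage 1: density-based clustering

For a point set $D$ and radius $\varepsilon$, the
$\varepsilon$-neighbourhood of $p$ is
$N_\varepsilon(p) = \{q \in D \mid d(p,q) < \varepsilon\}$ — note the
**strict** inequality, which this package follows exactly even though many
implementations use $\le$; two points exactly $\varepsilon$ apart are not
neighbours. $p \in N_\varepsilon(p)$ always holds, and the density
threshold *minPts* counts the point itself. A point is *core* when
$|N_\varepsilon(p)| \ge \text{minPts}$, *border* when it is not core but
lies in some core point's neighbourhood, and *noise* otherwise. Clusters
are the maximal density-connected sets; `dbscan()` grows them by
breadth-first expansion from each unassigned core point in index order.

Two conventions are worth stating:

* **Border ties.** A border point reachable from cores of two clusters is
  assigned to the first cluster discovered (deterministic index order), the
  classical behaviour; occurrences are counted and reported.
* **Distances** are Euclidean on the supplied planar (projected)
  coordinates. There is no geodesy anywhere in the package; if your
  coordinates are longitude/latitude, project them first.

Neighbourhood search uses a uniform grid of cell size $\varepsilon$ above
1,000 points and an exhaustive distance matrix below — an engineering
choice invisible in results.

Because the right $(\varepsilon, \text{minPts})$ pair is data-dependent,
`sensitivity_sweep()` reproduces the standard protocol of running the full
clustering over a small grid (the defaults mirror radii of 100/150/200
coordinate units crossed with density thresholds 5/10/15, the grid used in
practice for crash registries recorded in feet) and tabulating cluster,
core and noise counts. The package reports the table; it deliberately does
**not** auto-select parameters, because the choice involves judgment about
what a "reasonably sized" hotspot is on the ground. Core counts obey two
monotonicity laws the tests assert: non-decreasing in $\varepsilon$ at
fixed minPts and non-increasing in minPts at fixed $\varepsilon$.

Hotspot geometry is reported as the convex hull of each cluster's members
(`cluster_hulls()`, exported as GeoJSON). Clusters with fewer than three
non-collinear members yield a flagged degenerate segment or point rather
than a sliver polygon.

## Stage 2: the spatial lag binary probit

Let $y_i \in \{0, 1\}$ be the binarised severity (1 = injury or fatality)
and $x_i$ the covariate row. The latent-variable model is

$$Y^* = \rho W Y^* + X\beta + \varepsilon, \qquad
  \varepsilon \sim N(0, I_n), \qquad y_i = \mathbf{1}(Y_i^* > 0),$$

where $W$ is a row-standardised spatial weight matrix and $\rho$ the
spatial dependence parameter; at $\rho = 0$ the model reduces to the
standard binary probit. The error variance is fixed at 1 because it is not
identified in a binary model; this is not configurable.

### Spatial weights

The weight matrix connects individual crash observations (not areal
aggregates). The default rule is $k$-nearest-neighbour with $k = 5$:
registry descriptions of contiguity for point data are typically vague, and
kNN guarantees no isolated rows, which keeps the sampler's spatial lag
well-defined everywhere. A distance-band rule
($w_{ij} = 1$ iff $0 < d(i,j) < t$, strict, symmetric) is available;
observations it isolates keep zero rows — their spatial lag is the
degenerate weighted average 0 — and carry a warning rather than an error.
Distance ties in kNN break by ascending index, deterministically.

Row-standardisation divides each nonzero row by its sum, so $W Y^*$ is a
neighbour average. The eigenvalues of the standardised matrix are computed
once (dense, which bounds practical size to a few thousand observations)
and cached; they give both the admissible support
$(1/\lambda_{\min},\, 1)$ for $\rho$ and the log-determinant
$\ln|I - \rho W| = \sum_i \ln(1 - \rho\lambda_i)$ used at every
Metropolis step (complex conjugate pairs enter through their modulus, so
the sum is real).

### Sampling scheme

`fit_spatial_probit()` runs a Markov chain with three blocks per iteration:

* **Latent field** — single-site Gibbs in a fixed systematic scan. With
  $S = I - \rho W$ and $A = S'S$, the joint conditional of $Y^*$ is
  $N(S^{-1}X\beta,\, A^{-1})$, so each site's conditional is univariate
  normal with mean $y^*_i - h_i / A_{ii}$ and variance $1/A_{ii}$, where
  $h = A y^* - S'X\beta$ is maintained incrementally through sparse column
  updates — no linear solves inside the scan. The draw is truncated to
  $(0,\infty)$ when $y_i = 1$ and $(-\infty, 0]$ otherwise, so the
  latent-sign constraint holds at every draw by construction (and is
  re-verified on every retained draw).
* **Coefficients** — conjugate normal conditional under the prior
  $\beta \sim N(0, 100 I)$ (diffuse; configurable).
* **Spatial dependence** — random-walk Metropolis–Hastings for $\rho$
  under a uniform prior on its spectral support; proposals outside the
  support are auto-rejected. The proposal scale is tuned during burn-in
  toward 30–50% acceptance and frozen afterwards, keeping the post-burn-in
  chain a valid fixed-kernel MCMC.

Defaults are 6,000 iterations with 1,000 burn-in and no thinning — sized so
a full fit at $n \approx 400$ takes a couple of seconds and the package's
simulation studies run in minutes; raise them for final analyses. All
randomness flows through R's RNG, so `set.seed`-style seeds in
`mcmc_config()` give bitwise-reproducible chains. The non-spatial
`fit_probit()` is the classical truncated-normal data-augmentation Gibbs
sampler with the same conventions.

Posterior summaries report the mean, SD, Monte Carlo standard error
(SD$/\sqrt{\mathrm{ESS}}$, with ESS from initial-positive-sequence
autocorrelation truncation), and equal-tailed credible intervals; a
parameter is starred significant when its 95% interval excludes 0,
matching registry-table convention.

### Model comparison and the deviance plug-in

DIC is $\bar D + p_D$ with $p_D = \bar D - \hat D$. The binary deviance
needs a per-observation success probability. For the spatial model the
joint likelihood is an $n$-dimensional integral, so a plug-in is
unavoidable; this package uses the **exact marginal** of each observation:
under the latent model, $Y^*_i \sim N(\eta_i, s_i^2)$ marginally with
$\eta = S^{-1}X\beta$ and $s_i^2 = [S^{-1}S^{-\top}]_{ii}$, so
$p_i = \Phi(\eta_i / s_i)$. A tempting shortcut plugs the marginal mean
into a unit-variance $\Phi$; that mis-calibrates the spatial model (its
marginal latent variances exceed 1 whenever $\rho \ne 0$) and in our
simulation studies it erases the DIC advantage of the true spatial model.
The variance-normalised marginal is therefore the package's definition; it
reduces identically to $\Phi(x_i\beta)$ at $\rho = 0$. Probabilities are
clamped at $10^{-12}$ from either boundary, with clamp events counted. The
deviance is evaluated on thinned retained draws (default every 10th)
because each spatial evaluation costs a dense inverse.

A DIC difference above 10 is treated as decisive, the usual working rule;
`compare_models()` reports the preferred model and whether the difference
crosses that threshold.

### Marginal effects: two readings

Registry analyses of ordinal-coded categorical predictors sometimes read a
posterior-mean coefficient directly as a percentage-point change per
one-step change of the code (a mean of $-0.106$ reported as $-10.6\%$).
That arithmetic is not a conventional probit partial effect, but it is how
such tables are often narrated, so `marginal_effects()` reports it as
`paper_pct` alongside the orthodox average partial effect `ape`:
$\mathbb{E}[\phi(\eta_i/s_i)/s_i \cdot \beta_k]$ over observations and
draws, with the spatial feedback multiplier (row sums of $S^{-1}$) applied
in the spatial model. The two modes answer different questions and neither
is endorsed over the other; at $\rho = 0$ the `ape` mode coincides with the
non-spatial effect.

### Stepwise pruning

`stepwise_prune()` mirrors the practice of removing insignificant
parameters one at a time: each round drops the predictor whose credible
interval most widely covers zero (largest $\min(u, -\ell)$; ties to the
later column), refits, and stops when everything retained is significant.
The intercept is never removed, and the full removal log is returned. This
is a reporting convention, not a model-selection procedure with guarantees.

## Preprocessing conventions

* The older-driver filter is **inclusive** at the threshold (age 65 keeps
  65).
* Severity binarisation maps PDO to 0 and merges injury and fatality into
  1 — fatalities are typically a fraction of a percent of records, so the
  merge does not materially change the analysis. Records with missing
  severity are dropped with a logged count; unrecognised codes are an
  error naming the offending records.
* The Pearson collinearity screen defaults to $|r| \ge 0.7$ — a
  conventional cutoff, configurable — and greedily drops the later-listed
  member of each violating pair, so results are deterministic in the
  user's predictor order. Constant columns are dropped with a warning, not
  silently.
* The design matrix defaults to **ordinal** encoding (each integer-coded
  categorical enters as a single column), mirroring
  one-coefficient-per-variable registry tables; statistically orthodox
  dummy encoding against the 0/"Unknown" base level is available via
  `encoding = "dummy"`.

## The synthetic data generator

`synthetic_config()` + `generate_crash_table()` define the study
conditions the package is tested under:

* **Geometry**: circular hotspots (uniform on each disc) over a uniform
  background in a planar bounding box, with the true hotspot index stored
  per point. The default is three 200-unit discs of 60 points plus 120
  background points in a 10,000-unit box, echoing the dense-corridor
  geometry of urban crash maps at the radii the sweep grid probes.
* **Covariates**: the default schema reproduces the marginal category
  proportions of a published older-driver registry summary (crash type,
  at-fault/not-at-fault vehicle descriptors, road, weather, lighting,
  total vehicles), coded as small integers with 0 the "Unknown" level.
  Columns are drawn independently — the registry's joint dependence
  structure is not public and is not emulated, which is the main respect
  in which passing tests understate real-data difficulty (real collinear
  covariates are exercised separately through the screen's own tests).
* **Outcome**: the exact spatial lag probit DGP,
  $Y^* = (I-\rho W)^{-1}(X\beta + \varepsilon)$ by dense solve (exact at a
  few thousand points), binarised at zero, with latent values kept as
  ground truth. The default $\beta$ uses published posterior means of the
  significant predictors (e.g. crash type $-0.106$, road condition
  $-0.534$, intercept $1.541$) and 0 elsewhere, giving a realistic ~64%
  injury share; the default $\rho$ is 0.5. Ages are uniform on 55–95 so
  the age-65 filter genuinely removes records.

Non-goals: road-network-constrained point placement, temporal dynamics,
exposure weighting, and multinomial/ordered severity (the binary merge is
the modelling target).

### Test-design choices

Simulation fixtures use two DGP flavours deliberately:

* Recovery studies at the spec'd conditions ($n = 400$, $\rho = 0.5$,
  $\beta = (1, -1)$, kNN $k = 5$) for bias and coverage of the sampler.
* **Centred designs** ($\beta = (0, 1)$, ~50/50 outcomes) for the
  reduction-law and model-comparison studies. With unbalanced outcomes the
  spatial and non-spatial $\beta$ posteriors genuinely differ through the
  $\rho$–intercept coupling even for a perfect sampler, because $\rho$ is
  weakly identified in binary data at these sizes (posterior SD
  $\approx 0.15$ at $n = 400$); centring makes that coupling second-order,
  so the comparison isolates what it is meant to test. Sampler calibration
  is checked separately: across replicated $\rho = 0$ datasets the 95%
  interval for $\rho$ covers the truth at the nominal rate.

Problem sizes in the test-suite and acceptance studies ($n$ of 300–400,
5–20 replicates, 6,000 draws) are chosen so the full suite runs in minutes
on one core while leaving the statistical checks well-powered; they are the
package's own desk-scale conditions, and all scale upward by configuration.

## Numerical choices, degenerate inputs, limitations

* Deviance probability clamp $10^{-12}$; row-sum tolerance for
  standardised weights $10^{-12}$.
* $(I - \rho W)$ singularity (a proposed or configured $\rho$ hitting an
  eigenvalue reciprocal) raises an error naming $\rho$; Metropolis
  proposals outside the spectral support are auto-rejected, not errors.
* Empty point sets cluster to an empty result; all-coincident points form
  one cluster when minPts allows; an empty predictor list fits
  intercept-only models with a warning; an all-0 or all-1 response is an
  error (no probit is estimable).
* Degenerate hulls are flagged, never silently inflated to polygons.
* Possible separation (a coefficient drifting to large magnitude) is
  detected heuristically and surfaced as a warning in the fit.
* Dense eigendecomposition and dense marginal-variance inverses bound the
  comfortable problem size to a few thousand observations; beyond that the
  package is the wrong tool without sparse spectral methods.
* The DIC plug-in is a product of exact per-observation marginals, not the
  joint likelihood; model comparisons inherit that approximation (both
  models are scored by the same rule).
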