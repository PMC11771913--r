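# crashspot

Two-stage geospatial and econometric analysis of road-crash injury
severity for older drivers, for road-safety analysts working with
point-referenced crash registries:

1. **Hotspot identification** — a from-scratch DBSCAN over planar crash
   coordinates, with the radius/density sensitivity-sweep protocol and
   convex-hull (GeoJSON) export of each hotspot.
2. **Severity modelling** — a Bayesian *spatial lag binary probit* for the
   binarised outcome (0 = property damage only, 1 = injury or fatality),
   estimated by MCMC with latent-variable augmentation, compared against a
   non-spatial Bayesian probit by DIC.

A synthetic-data module generates both stages' inputs from a known
spatial-lag-probit data-generating process (planted hotspots, registry-like
coded covariates, stored latent field), so the whole pipeline is testable
without access to any crash registry.

## The model

With $y_i = \mathbf 1(\text{injury or fatality})$, covariates $X$, and a
row-standardised spatial weight matrix $W$ linking crash observations
(default: 5 nearest neighbours):

$$Y^* = \rho W Y^* + X\beta + \varepsilon,\qquad
  \varepsilon \sim N(0, I_n),\qquad y_i = \mathbf 1(Y_i^* > 0).$$

$\rho = 0$ reduces the model to the standard binary probit. Estimation
cycles truncated-normal Gibbs updates of the latent field, the conjugate
normal conditional for $\beta$ (prior $N(0, 100I)$), and random-walk
Metropolis–Hastings for $\rho$ on its spectral support
$(1/\lambda_{\min}, 1)$, with $\ln|I-\rho W|$ from cached eigenvalues.
DBSCAN follows the printed definitions literally: strict
$d(p,q) < \varepsilon$, self-inclusive neighbourhoods, *minPts* counting
the point itself. See the methods vignette
(`vignettes/crash-hotspots-and-spatial-probit.Rmd`) for every convention
and numerical choice.

## Worked example

Simulate a two-hotspot crash table with one real predictor (`z`) and one
noise predictor, then run the full pipeline:

```r
library(crashspot)

syn <- synthetic_config(
  hotspots = data.frame(x = c(2000, 7000), y = c(2000, 7000),
                        radius = 60, n = 50),
  background_count = 60, bounding_box = c(0, 0, 10000, 10000),
  covariates = list(cov_continuous("z"), cov_continuous("noise")),
  beta = c(0, 1, 0), rho = 0.4, seed = 42)

cfg <- pipeline_config(
  input = syn, age_threshold = 65,
  eps_values = c(40, 60, 80), min_pts_values = c(3, 5, 8),
  chosen_eps = 60, chosen_min_pts = 5,
  predictors = c("z", "noise"),
  mcmc = mcmc_config(seed = 42))

report <- run_pipeline(cfg)
#> simulate: 160 records (seed 42)
#> older-driver filter (age >= 65): 116 records
#> binarize severity: 116 records, 51 injury/fatality
#> sensitivity sweep: 9 (eps, minPts) cells
#> clustering at (eps = 60, minPts = 5): 2 cluster(s), 41 noise, 0 border tie(s)
#> collinearity screen (|r| >= 0.7): retained 2 of 2 predictors
#> design matrix: 116 x 3 (ordinal encoding)
#> weights: knn (k = 5), 0 isolated row(s), rho support (-2.122, 1.000)
#> probit fit: 5000 retained draws
#> spatial probit fit: rho mean 0.072, acceptance 0.43
#> probit preferred (DIC 105.041 vs 105.649); difference 0.608 is below the decisive threshold of 10

summary(report$fit_spatial)
#>     parameter        mean        sd        mcse  bci_lower  bci_upper significant
#> 1 (Intercept) -0.23524325 0.1594556 0.006803939 -0.5858366 0.04649071       FALSE
#> 2           z  1.41807856 0.2442168 0.011637624  0.9785803 1.91644072        TRUE
#> 3       noise -0.01081494 0.1392472 0.004020405 -0.2834505 0.26434887       FALSE
#> 4         rho  0.07244534 0.2112064 0.013925267 -0.3709298 0.41560512       FALSE
```

Reading the output: both planted hotspots are recovered at every sweep cell
(the 41 noise points are the true background); the true predictor `z`
(generating coefficient 1) is the only significant covariate, while the
noise predictor's interval straddles 0. At this small n the spatial
dependence parameter is weakly identified — its interval covers both 0 and
the generating value 0.4 — and the DIC difference between the two models is
accordingly indecisive, which is exactly how such a comparison should be
read (differences above 10 are treated as decisive). When an output
directory is set, the run also writes per-point cluster labels, hotspot
polygons as GeoJSON, the sweep table, both fit reports, a comparison
verdict and a run log.

A thin command-line front end over the same functions is installed at
`inst/cli/crashspot.R` with `simulate`, `cluster`, `fit` and `pipeline`
subcommands.

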