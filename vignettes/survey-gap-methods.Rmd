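---
title: "Measuring survey gaps in presence-only occurrence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring survey gaps in presence-only occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Presence-only occurrence records — museum specimens, literature records,
database downloads — are the raw material of most biodiversity analyses in
megadiverse regions, and they are not a random sample of anything. Records
concentrate near roads and cities, inside protected areas, in regions
perceived as species-rich, and on species that standard field methods catch
easily. `surveygap` quantifies both axes of this bias for a gridded study
region and turns the result into a map of where new survey effort would
help most.

The package treats the pooled records of all species as a proxy for survey
effort: a grid cell is *sampled* if it holds at least one record of any
species, *un-sampled* otherwise. Everything downstream builds on that
classification.

## Pipeline overview

1. **Gridding** (`build_grid`, `assign_records`, `range_size`,
   `richness_overlay`, `covariate_build`, `screen_and_standardize`): a
   lon/lat lattice (default 5 arc-minutes) clipped to the study boundary by
   the centroid rule; records fall into half-open cells; species range maps
   are rasterized to cells; seven per-cell covariates describe species
   richness (range-map richness, elevational heterogeneity, protected-area
   cover), accessibility (road length, urban cover, population density) and
   security (homicide rate).
2. **Sampling activity** (`thiessen`, `large_polygon_summary`): Thiessen
   (Voronoi) polygons of the sampled-cell centroids; a large polygon means
   a region whose faunal knowledge rests on one sampled cell.
3. **Ecoregion bias** (`estimate_p`, `bias_d`, `chisq_representativeness`,
   `ecoregion_bias`): a randomization-calibrated z-like score per
   ecoregion,
   `Bias_d = (n_d - p_d N) / sqrt(p_d (1 - p_d) N)`,
   with `p_d` estimated as the mean ecoregion share of 100 random draws of
   `N` land cells, plus an overall chi-squared test of representativeness.
4. **Taxonomic bias** (`fit_powerlaw`, `tukey_guild_contrasts`,
   `guild_slopes`): sampled cells `y` against range size `x` as a power law
   `y = a x^b`, fitted on log-log axes per foraging guild (open-, edge-,
   narrow-space foragers — a surrogate for how easily standard capture
   methods detect a species), with sequential F-tests, Tukey-style guild
   contrasts, and per-guild exponents classified against `b = 1`.
5. **Spatial regressions** (`build_adjacency`, `fit_icar`, `rhat`,
   `summarize_icar`): Bayesian GLMs with an intrinsic conditional
   autoregressive (ICAR) spatial random effect, fitted by a purpose-built
   Metropolis-within-Gibbs sampler — a Bernoulli-logit model for presence
   of records over all land cells, and a Poisson-log model for record
   counts over sampled cells (a two-part design for zero-inflated data).
6. **Threat overlay** (`build_threats`, `univariate_threat_car`,
   `priority_map`): 2050s-minus-current changes in temperature,
   precipitation, forest and cropland cover; univariate presence-vs-threat
   spatial models; and a composite priority score for un-sampled cells.

A synthetic-landscape generator (`sim_config`, `make_landscape`,
`make_species_pool`, `simulate_records`, `make_threats`,
`simulate_study`) supplies data with known ground truth for every stage.

## The spatial model

For cell $i$ with covariates $x_i$ the linear predictor is
$\eta_i = \alpha + x_i^\top\beta + \phi_i$, with
$y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\eta_i))$ for presence or
$y_i \sim \mathrm{Poisson}(e^{\eta_i})$ for counts. The spatial effect
$\phi$ carries the intrinsic CAR (pairwise-difference) prior
$$p(\phi \mid \tau) \propto \tau^{(n-C)/2}
  \exp\Big(-\frac{\tau}{2}\sum_{i\sim j}(\phi_i-\phi_j)^2\Big),$$
over queen (8-neighbor) adjacency, where $C$ is the number of connected
components: each $\phi_i$, given its neighbors, is normal with mean the
neighbor average and variance $1/(\tau m_i)$. Priors follow the common
"as non-informative as practical" choice for these models: improper
uniform intercept, $\beta_j \sim N(0, 1000)$, and a Gamma prior on $\tau$
with mean 1 and variance 1000, i.e. shape 0.001 and rate 0.001 by moment
matching.

### Sampler design

`fit_icar` is a Metropolis-within-Gibbs sampler written in C++:

* $\tau$ by its conjugate Gamma full conditional, shape
  $a_0 + (n_\mathrm{eff}-C)/2$ and rate $b_0 + \tfrac12\sum_{i\sim j}(\phi_i-\phi_j)^2$,
  with $n_\mathrm{eff}$ the non-isolated nodes;
* each $\phi_i$ by single-site Metropolis, alternating sweeps of an
  adaptive random walk with sweeps of an independence proposal drawn from
  the ICAR full conditional $N(\bar\phi_{\partial i},\, 1/(\tau m_i))$.
  The independence-proposal scale is capped at 1: when $\tau$ is small the
  uncapped proposal becomes arbitrarily wide and single-site chains can
  wander into a metastable regime where $\phi$ interpolates a binary
  response exactly and $\tau$ collapses — a known hazard of vague Gamma
  precision priors on intrinsic CAR models at small $n$. The cap keeps
  proposals sane there, and the proposal-density correction then actively
  pulls stray $\phi_i$ back toward the neighbor mean; when $\tau$ is
  moderate the cap is inactive and the proposal is the exact full
  conditional (prior terms cancel in the acceptance ratio);
* $\alpha$ and $\beta$ by adaptive random-walk Metropolis (scales tuned
  toward 44% acceptance during burn-in only);
* after every sweep $\phi$ is recentered: the global mean moves into the
  improper-uniform intercept (likelihood-invariant on a connected graph)
  and each connected component is centered; isolated cells carry
  $\phi_i = 0$.

Chains start overdispersed: $\beta$ jittered $N(0,1)$ and $\tau$ cycled
through 0.1, 1, 10. Convergence is summarized by the potential scale
reduction factor; any parameter above 1.1 sets a non-convergence flag.
All randomness flows through R's RNG, so a seed makes fits bit-reproducible.

Two schedules are built in: the published-style `"full"` schedule
(3 chains × 100,000 iterations, 50,000 burn-in, thin 10) and a `"desk"`
schedule (3 × 5,000, 2,500 burn-in, thin 5) sized for tests and
simulation studies on grids of a few hundred cells.

### Checking the sampler

The test suite checks the machinery against independent oracles rather
than against itself:

* the ICAR log-density against a dense generalized-inverse multivariate
  normal evaluation on small graphs;
* the $\tau$ full conditional against numerical normalization of the joint
  density over a $\tau$ grid on a 4-node cycle;
* exact ICAR draws (`sample_icar_phi`, by eigendecomposition of the graph
  Laplacian with null eigenvectors removed) against the generalized
  inverse covariance;
* with the spatial effect disabled, posterior means against a
  maximum-likelihood logistic fit. This comparison is made in the
  weak-effect regime (true coefficients of magnitude ≲ 0.2 at 200 cells)
  because that is where the Bayes-vs-ML agreement it asserts holds to
  within Monte Carlo error: with strong effects the posterior mean under a
  flat prior differs from the MLE by a skewness term of order
  $0.05\,\hat\beta$, which a well-mixed chain resolves. The Monte Carlo
  standard error uses effective sample sizes from Geyer's initial positive
  sequence estimator;
* full-model simulations (400 cells, known $\beta$, $\tau$) for 95%
  credible-interval coverage of $\beta$.

$\tau$ itself is weakly identified at a few hundred Bernoulli
observations; only the coefficient intervals are calibrated quantities at
that size, and that is what the recovery checks assert.

## The synthetic generator

`make_landscape` builds a fully-land lattice (default 30 × 30 cells at 5
arc-minutes), grows the requested number of contiguous ecoregions (default
7) by multi-source random-frontier expansion, and draws seven covariate
surfaces by repeatedly smoothing white noise with the neighbor-averaging
kernel, then mapping them onto plausible scales (counts, meters,
percentages, densities). `make_species_pool` draws range sizes
log-uniformly (default between 1 cell and the whole grid) and grows each
range as a connected blob by uniform random frontier expansion —
contiguous, like a rasterized range polygon. Guild proportions default to
20% open-, 45% edge-, 35% narrow-space foragers, an assemblage-like mix.
`simulate_records` exponentiates $\alpha + x^\top\beta + \phi$ with an
exact ICAR draw for $\phi$ and emits per-species Poisson counts thinned by
guild detectability (defaults 0.3/0.5/1.0 for open/edge/narrow,
reflecting that narrow-space foragers are the easiest to mist-net), with
record coordinates jittered uniformly within the cell so records re-grid
exactly.

When a per-guild power-law exponent `b_target` is requested, per-species
detection is calibrated so the per-cell sampling probability is
$p_s = a\,x_s^{\,b-1}$ with $a$ set so the largest probability in the
guild is 0.9; the expected sampled-cell count then follows
$a\,x^{\,b}$ exactly. Exponent-recovery simulations use a range-size floor
(`range_min = 25` cells) because a log-linear fit needs expected sampled
counts comfortably above zero, and real bat ranges rasterize to hundreds
of cells; the floor is a realism choice, not a tuning knob.

What the generator does **not** emulate: spatial duplication of museum
records, georeferencing error, taxonomic misidentification, coastline and
island geometry, or covariates measured with error. Tests passing on this
generator show the estimators are correct under the stated model, not
that real archives satisfy the model.

An optional negative-binomial knob (`nb_size`) adds overdispersion to
per-cell counts; there is no field-derived default, so Poisson is the
default generating process.

## Numerical and design choices

* **Cell membership** is by centroid for land, ecoregion and range
  assignment (one unambiguous label per cell; an any-overlap rule is
  available for ranges via `rule = "intersect"`), and record-to-cell
  mapping uses half-open intervals, west/south inclusive, so boundary
  records are never double-counted.
* **Cell areas** use the spherical rectangle formula with R = 6371 km; a
  5-arc-minute cell is ~78–86 km² at subtropical latitudes.
* **Thiessen polygons** are computed by half-plane intersection in a
  Lambert azimuthal equal-area projection centered on the region, then
  clipped to the boundary, so reported km² are honest and the polygons
  tile the region to well under 0.1%. Geodesic Voronoi is out of scope.
  For multi-ring boundaries, areas sum over all rings but each feature's
  exported outline is its largest clipped piece.
* **Randomization null**: random cell sets are drawn without replacement
  (a cell cannot be sampled twice); chi-squared expected values use the
  replicate-mean `p_d · N` with `df = k − 1` (a single-set alternative is
  exposed). Without-replacement drawing makes the test slightly
  conservative when `N` is an appreciable fraction of the land cells.
* **Power-law model**: natural logs (the exponent is base-invariant);
  species with zero sampled cells are excluded with a logged count; guild
  contrasts are evaluated at the centered mean of log range size where
  they equal intercept differences; adjusted p-values default to the
  single-step multivariate-t method (`multcomp::glht`), with the classical
  studentized-range HSD available for comparison.
* **Count model** for records on sampled cells is Poisson-log by default —
  the simplest standard CAR count model; the response being ≥ 1 on sampled
  cells, a zero-truncated variant is a natural refinement but is not the
  default reading.
* **Adjacency** is queen by default (rook available); the count model's
  graph over sampled cells only is typically disconnected, handled by
  per-component centering and $\phi = 0$ on isolated cells.
* **Threat variables**: land-class proportions are computed before
  differencing; the univariate models use the signed change, while the
  composite priority score counts only the harmful direction
  (deforestation, farmland expansion) and takes the mean of the four
  standardized threat magnitudes; priority cells are the un-sampled cells
  in the top fraction (default 10%) of that score, ties broken by cell id.
  The composite rule is this package's operationalization — narrative
  "under-surveyed and threatened" designations have no canonical formula.

## Problem sizes

The test suite and the acceptance script run at desk scale: landscapes of
400–3,600 cells, pools of up to 500 species, MCMC on the desk schedule,
20-replicate recovery studies. These sizes were chosen so the whole suite
exercises every stage in a couple of minutes while keeping each
statistical check adequately powered; all of them scale up by changing
`sim_config` and `icar_config` arguments.

## Known limitations

* Geometry is planar in lon/lat except where noted; polygons crossing the
  antimeridian or poles are unsupported, and invalid polygons are not
  repaired.
* The ICAR model's precision is weakly identified for binary data on
  small lattices; interpret $\tau$ posteriors cautiously and rely on the
  convergence flag.
* `screen_and_standardize` flags collinear pairs but does not choose which
  variable to drop; that remains an analyst decision.
* The Thiessen map treats all sampled cells equally regardless of how many
  records they hold; it is a map of presence of effort, not intensity.
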