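---
title: "Open-population line-transect SCR: model, sampler, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-population line-transect SCR: model, sampler, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it fits, the
choices made where the design was genuinely open, and what the bundled
validation machinery does and does not demonstrate.

## The hierarchical model

`lineSCR` targets studies in which transect lines are surveyed repeatedly
across a season, detected individuals are identified (photo-id, tags,
genotype) and their locations recorded, and the population is open
between primary periods. The canonical application shape is an aerial
survey program for a migratory marine mammal: two aircraft types with
different detection profiles, a coastal study area gridded into
10 km × 10 km pixels, and remotely sensed covariates (sea-surface
temperature, wind, depth) that shift over the season.

Four linked submodels are fit jointly; all symbols below are per
individual `i`, pixel `g`, primary period `t`, occasion `k`.

**Dynamics.** A Jolly–Seber superpopulation formulation with data
augmentation: the `n` observed individuals are padded to `M` candidate
individuals, which implies a discrete Uniform(0, M) prior on abundance at
`t = 1`. Presence follows
`z[i,t] ~ Bern(phi[t-1] z[i,t-1] + gamma[t] (1 - z[i,t-1]))`, with
`gamma[1]` the fraction of `M` present initially. For a migratory study
area, `gamma` is arrival and `phi` is persistence; individuals may leave
and re-enter, and re-entry shares `gamma` with initial entry (the
single-entry restriction and separate re-entry probabilities are not
implemented). On the logit scale `gamma` is quadratic and `phi` linear in
the standardized period index — a deliberately small parameterization for
a seasonal pulse of arrivals and departures.

**Density.** Activity centers live on the discretized state-space:
`log E(D[g,t]) = sum_j beta_j X[j,g,t]` with no intercept, because the
dynamics model already fixes total abundance; the density model only
allocates it. `s[i,t]` is categorical with probabilities proportional to
`E(D[g,t])`, independently across periods (appropriate for a highly
mobile species; random-walk or static centers are out of scope). Dome-
shaped responses are expressed by supplying a squared companion column in
the covariate stack — the model itself stays strictly linear in its
columns.

**Movement.** Given `s[i,t]`, the occupied pixel on an occasion has
log-kernel `-d^2/(2 sigma_move^2) + sum_j beta_j X[j,g,t]` (distances
between pixel centers), then the exact location is uniform within the
pixel. The habitat term makes space use a resource-selection surface
rather than a symmetric bivariate normal, and masked pixels can never be
used. Density and movement share `beta` and share the grid, matching the
canonical application; both constraints are structural in this
implementation.

**Detection.** `mindist` is the distance from the individual's location
to the nearest point of the nearest transect segment surveyed on the
occasion, computed by clamped projection (see *Numerical choices*).
The platform that flew the nearest segment selects a half-normal or
hazard-rate detection function; `p0`, detection on the line itself, is
estimated rather than assumed 1, which is the decisive difference from
conventional distance sampling for animals that may be unavailable
(diving) when the platform passes. Occasions without effort contribute
no detection opportunity (`p = 0`).

**Groups.** Any of (`beta_gamma`, `beta_phi`, `sigma_move`, `p0`) may be
group-specific; the shape of the detection function and the habitat
coefficients are shared. Membership is a latent categorical variable with
a flat Dirichlet prior constructed from Gamma(1,1) weights; the weights
are sampled by their Dirichlet(1 + counts) full conditional, which is
equivalent by the Gamma–Dirichlet construction.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Prior (default bounds) |
|---|---|---|---|
| `beta_j` | habitat effect on log density and log space use | per sd of covariate | Uniform(−10, 10) |
| `sigma_move` | movement scale around the activity center | distance units | Uniform(0, state-space diameter) |
| `p0` | detection probability at `mindist = 0` | probability | Uniform(0, 1) |
| `sigma` (hn/hr) | detection scale | distance units | Uniform(0, diameter) |
| `b` (hr) | hazard-rate shoulder sharpness | — | Uniform(1, 50) |
| `beta_gamma` | arrival: intercept, linear, quadratic in time | logit | Uniform(−10, 10) |
| `beta_phi` | persistence: intercept, linear in time | logit | Uniform(−10, 10) |
| `M` | augmentation bound | individuals | fixed by the analyst |

Coordinates are assumed pre-scaled so that distances are O(1)–O(10)
(1 unit = 10 km works well for marine grids); `read_study(scale =)`
rescales on load, exactly once. Guidance for `M`: at least 1.5 × the
observed `n`, raised if the posterior of any `N_t` crowds `M` (the
sampler cannot exceed it, so a pile-up at `M` signals truncation, and
`augment_histories()` warns when `M = n`).

Time is standardized with the population (divisor-`T`) standard
deviation so that the vector of period indices has exactly unit
descriptive sd; `standardize_time(sample_sd = TRUE)` switches to the
divisor-`T−1` convention. Covariates are standardized pooling over
pixels **and** periods — a covariate that rises seasonally should carry
that signal, which per-period standardization would erase. Squared
companion columns are built from the standardized base column and then
standardized themselves, so every column of the stack enters the linear
predictor on a common scale.

## The sampler

`scr_fit()` runs a Metropolis-within-Gibbs sweep: random-walk Metropolis
blocks for `beta` (jointly), each `sigma_move`, each detection scalar,
and each group's `beta_gamma` / `beta_phi`; Gibbs draws for activity
centers, group memberships and the Dirichlet weights; and for the latent
states two likelihood treatments:

* **latent** (default): every present-but-undetected individual-occasion
  carries an explicit location, updated by independence Metropolis with
  the movement kernel as proposal (acceptance ratio `(1−p')/(1−p)`).
  Presence flips are joint (z, locations) Metropolis moves that propose
  fresh locations from the movement prior, so the acceptance ratio is
  the product of `(1−p)` terms times the dynamics prior odds. This is
  the model exactly as written.
* **marginalized**: locations are integrated out,
  `P(undetected | s) = sum_g pi_move[g] (1 − pbar[g])`, where `pbar`
  approximates the within-pixel average detection probability by an
  m-point quadrature (`quad_m = 1`: pixel center; `2`: a 2 × 2 rule).
  Presence and activity-center updates become exact Gibbs draws. This is
  a large runtime lever when detections are sparse; its only
  approximation is the quadrature, which is negligible once the
  detection scale exceeds the pixel side (the test suite holds the two
  modes to within ~10% of each other on posterior mean abundance under
  that condition).

Individuals with `z = 0` skip movement and location work — their
likelihood contribution is 1 — and their activity centers are refreshed
from the prior, which leaves the posterior unchanged while keeping the
`beta` update's bookkeeping uniform.

Proposal scales adapt toward a 0.2–0.5 acceptance band during burn-in
only and are frozen afterwards, preserving the stationary distribution.
Proposals outside the Uniform prior bounds are rejected outright (a
valid Metropolis move against a flat prior with hard bounds).

## Numerical choices

- **Point-to-segment distance** uses the clamped projection parameter
  `u = clamp(((p−a)·(b−a))/|b−a|², 0, 1)`; it is defined for every
  orientation including due north–south segments (where a slope/intercept
  formulation breaks down), is symmetric in the endpoints (so no
  westernmost-first bookkeeping), and is exact — the tests compare it to
  dense brute-force sampling along the segment.
- **Hazard-rate at zero**: the printed form has `(d/sigma)^{-b}`
  undefined at `d = 0`; the implementation takes the continuous limit
  `p(0) = p0`.
- **Pixel membership** uses half-open squares; a point on a shared edge
  belongs to the higher-index pixel, and the outer north/east boundary is
  closed so the bounding box is fully covered.
- **Log-sum-exp stabilization** everywhere a kernel is normalized
  (density and movement simplexes), so `sigma_move` as small as 10⁻²
  or as large as 10⁶ cannot underflow or overflow.
- **Equidistant platforms**: if two segments from different platforms tie
  for nearest (probability zero for continuous locations), the lowest
  segment index wins, deterministically.
- **Degenerate covariates** (no variation over pixels and periods) are
  rejected at standardization rather than silently producing NaNs.

## The simulator and the validation suite

`scr_scenario()` defaults define the package's "desk" study: a 15 × 15
grid of unit pixels (G = 225), T = 5 primary periods of K = 3 occasions,
M = 150, one group and one (half-normal) platform, two smooth covariates
with squared companions, and 6 parallel east–west transects per occasion
whose north–south offset re-randomizes each occasion. True parameters
(`beta = (0.4, 0.3, −0.3, −0.2)`, `sigma_move = 2`, `p0 = 0.7`,
detection scale 0.6 pixel, arrival quadratic `(−0.8, 0.3, −0.3)`,
persistence `(1.2, −0.3)`) give a seasonal pulse from ~20 to ~80 present
individuals — sizes a desk machine refits in minutes. Covariate surfaces
are random low-order spatial polynomials plus a seasonal shift plus pixel
noise: smooth like remotely sensed fields, but with none of the spatial
autocorrelation structure, missingness, or interpolation artifacts of
real oceanographic rasters. Passing recovery tests on these surfaces
therefore demonstrates the estimator, not the data-preparation pipeline;
real applications still need careful covariate prep (the loader's
neighbor-mean interpolation of missing pixels is the user's
responsibility to configure sensibly).

Validation is layered, cheapest to most expensive, and the problem sizes
below are the package's chosen test sizes:

1. **Unit oracles** — brute-force or closed-form checks for every
   geometric, link, and counting operation.
2. **Exhaustive enumeration** — on a 2 × 2-grid, two-period micro
   instance with all parameters fixed, the per-individual posterior over
   (presence, activity centers) is summed exactly over all
   configurations; sampler marginals must match within Monte-Carlo
   error. This check caught a real detailed-balance bug during
   development (a presence-flip pass that gave some individuals two
   proposals per sweep), which is precisely the class of error it
   exists to catch.
3. **Successive-conditional calibration** (`successive_conditional_sim`)
   — iterating "simulate data given current parameters, advance
   parameters by MCMC given those data" must leave the prior invariant;
   the monitored marginals of `sigma_move`, `p0` and the arrival
   intercept are compared to independent prior draws. The calibration
   loop deliberately does not adapt proposal scales (a changing kernel
   would invalidate the argument), so the scales passed in must be large
   enough to traverse the prior in a few sweeps.
4. **Parameter recovery** — replicate simulated studies are refit and
   95% credible intervals compared to the generating values with a
   binomial coverage test, plus a <10% bound on the average relative
   bias of posterior-mean abundance. The test suite runs 3 replicates at
   a reduced scale (12 × 12 grid, T = 4, M = 80, 2 chains × 1500
   iterations); `scripts/acceptance.R` runs one replicate at the full
   desk scale with 3 chains × 2000 iterations.

Convergence is monitored with split-chain R-hat (each chain's kept draws
halved, so within-chain trends register); the conventional 1.1 threshold
is used by the CLI `check` command. Individual habitat coefficients can
show elevated R-hat when squared companions induce collinearity, while
the composed quantities (density surfaces, abundance) mix well — judge
convergence on the quantities of scientific interest, not only on raw
coefficients.

## Design decisions and limitations

- **Crossed detection baselines.** With multiple groups and platforms,
  `p0` is parameterized per group × platform, each with its own
  Uniform(0, 1) prior, rather than additively on the logit scale. The
  additive layout saves one parameter but cannot carry a uniform prior
  on each baseline; with the crossed layout the stated prior is exact.
  Nothing else in the likelihood changes.
- **Shared `beta` between density and movement** is structural here, as
  is the shared state-space grid. Decoupling them is a modeling
  extension, not a configuration flag.
- **No location measurement error**: observed sighting coordinates are
  treated as exact, as the observation model specifies. Survey programs
  that estimate locations from angle/distance should assess that error
  upstream.
- **No survey-condition covariates on detection** (visibility, sea
  state); programs that fly in marginal conditions would need them.
- **Filtering rules** in the loader are generic: duplicate
  same-occasion detections keep the first record (with a warning; no
  time-of-day column is modeled), and an optional `max_dist` filter
  guards against far outliers that would otherwise stretch the detection
  function. Application-specific exclusions (off-watch segments,
  dependent calves, verification surveys) are data preparation, done
  before the files reach the loader.
- **Runtime**: the sampler is vectorized base R. The marginalized mode
  and the pixel-count of the grid are the two main levers; fitting the
  desk scenario (G = 225, M = 150, 3 chains × 2000) takes on the order
  of minutes, and scaling much beyond a few thousand pixels would call
  for a compiled kernel.
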