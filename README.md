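# lineSCR

Open-population spatial capture–recapture (SCR) for **line-transect
surveys** of uniquely identifiable individuals — e.g. aerial
photo-identification surveys of whales on a migratory ground. From the
transect lines flown on each occasion, the locations of identified
sightings, and gridded habitat covariates, `lineSCR` jointly estimates:

- **density** of latent activity centers across a discretized state-space,
  driven by habitat covariates;
- **space use / movement** around activity centers, with a
  resource-selection kernel on the same covariates;
- **population dynamics** — per-period abundance, arrival (recruitment)
  and persistence (survival) probabilities, and superpopulation size —
  via a Jolly–Seber superpopulation model with data augmentation;
- **detection**, distance-sampling style, with an *estimable* probability
  of detection on the line.

The package contains a forward simulator for the full hierarchical model,
a bespoke Metropolis-within-Gibbs sampler, convergence diagnostics, and
CSV readers/writers plus a small command-line wrapper
(`inst/cli/linescr`).

## The model

The study runs over primary periods `t = 1..T` (population open between
them) each containing secondary occasions `k = 1..K_t` (population closed
within). For `M` data-augmented individuals:

- **Presence**: `z[i,1] ~ Bern(gamma_1)` and
  `z[i,t] ~ Bern(phi_{t-1} z[i,t-1] + gamma_t (1 - z[i,t-1]))`, with
  `logit(gamma_t)` quadratic and `logit(phi_t)` linear in standardized
  time. Abundance is `N_t = sum_i z[i,t]`, recruitment
  `R_t = sum_i (1 - z[i,t-1]) z[i,t]`; re-entry is allowed.
- **Density**: the state-space is a grid of `G` pixels;
  `log E(D[g,t]) = sum_j beta_j X[j,g,t]` (no intercept — the dynamics
  model sets total abundance), and activity centers are
  `s[i,t] ~ Categorical(E(D[.,t]) / sum E(D[.,t]))`, independent across
  periods. Realized density is the count of present activity centers per
  pixel divided by pixel area.
- **Movement**: on each occasion the individual occupies pixel `g` with
  probability proportional to
  `exp(-d(g, s[i,t])^2 / (2 sigma_move^2) + sum_j beta_j X[j,g,t])`, and
  an exact location uniform within that pixel.
- **Detection**: `p[i,k,t]` is a half-normal
  (`p0 exp(-mindist^2 / 2 sigma^2)`) or hazard-rate
  (`p0 (1 - exp(-(mindist/sigma)^-b))`) function of `mindist`, the
  distance from the individual's location to the closest point on the
  closest transect segment surveyed that occasion; the form follows the
  platform that flew the nearest segment. `y[i,k,t] ~ Bern(z[i,t] p)`,
  and detected locations are observed exactly.
- **Groups**: demographic groups (`V ≥ 2`) may differ in arrival,
  persistence, movement scale, and baseline detection `p0`; membership is
  data when recorded and a latent variable otherwise, with a flat
  Dirichlet prior built from Gamma(1,1) weights.

All parameters get Uniform priors with configurable bounds. Coordinates
are planar and pre-scaled (a convenient convention is 1 unit = 10 km).

## Worked example

Simulate a small study from the generative model and refit it:

```r
library(lineSCR)
sc <- scr_scenario(n_x = 8, n_y = 8, T_periods = 3, K = 2, M = 40,
                   sigma_move = 1.5, n_transects = 4,
                   det = det_params(list(form = "hn", p0 = 0.7, sigma = 0.6)))
sim <- simulate_study(sc, seed = 1)
sim$study
#> Line-transect SCR study: 21 individuals, 44 detections, T = 3, G = 64

fit <- scr_fit(sim$study, M = 40, n_iter = 3000, n_burnin = 1500,
               n_chains = 2, seed = 2)
s <- summary(fit)
s[s$parameter %in% c("sigma_move.1", "p0.1.1", "det_sigma.1",
                     "N.1", "N.2", "N.3", "Nsuper"), ]
#>       parameter   mean     sd   q2.5  q97.5 rhat
#> 5  sigma_move.1  1.554 0.3384  1.086  2.374 1.04
#> 6        p0.1.1  0.839 0.1005  0.628  0.992 1.01
#> 7   det_sigma.1  0.477 0.0841  0.367  0.674 1.01
#> 13          N.1  5.939 1.7470  4.000 10.000 1.01
#> 14          N.2 14.741 3.1513 11.000 23.000 1.13
#> 15          N.3 24.960 3.1979 20.000 33.000 1.01
#> 19       Nsuper 25.513 2.9744 21.000 33.000 1.00

sim$truth$N                     # generating abundances: 5 15 21
sim$truth$Nsuper                # generating superpopulation: 26
```

Every 95% interval above covers its generating value: 21 individuals were
observed, the model estimates ~26 ever used the area, abundance grew from
~6 to ~25 across the three periods, the movement scale is estimated near
its generating value of 1.5 pixel widths, and detection on the line is
estimated (not assumed) near 0.8. `fit$rd_mean` holds the posterior-mean
realized-density surface per period.

Real data are read from three CSVs (transects, sightings, covariates; see
`?read_study`), and the same workflow is scriptable from a shell via
`inst/cli/linescr simulate | fit | summarize | check`.

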