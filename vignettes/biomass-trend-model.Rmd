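---
title: "Modelling interval-aggregated malaise-trap biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interval-aggregated malaise-trap biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why this model

Malaise-trap monitoring produces one weight per bottle: the total wet mass
of all insects caught while the bottle was exposed, typically for one to
several weeks. Three properties of such data defeat the obvious
regressions. First, the response is an *interval aggregate*: a catch sums
an unknown daily series, and exposure lengths differ between catches, so
log-transforming the total mixes exposure with abundance. Second, daily
biomass is positive and right-skewed, and its dispersion grows with its
level. Third, sites are short panels — most locations are sampled in one
or two seasons — so year-to-year change must be estimated across sites
while a random intercept absorbs persistent site differences.

The package therefore models the catch as normal about the **sum of a
latent daily biomass** over the inclusive exposure interval:

$$m_j \sim N\!\Big(\textstyle\sum_{t=\tau_1(j)}^{\tau_2(j)} z_{t,s,k},\;
\sigma^2_j\Big), \qquad z_{t,s,k} = e^{y_{t,s,k}}$$

$$y_{t,s,k} = c + \log(\lambda)\,k + X\beta + u_s, \qquad
u_s \sim N(0, \sigma^2_{site})$$

$$\sigma^2_j = \textstyle\sum_t e^{2 y_{t,s,k} + v}\,(e^{v} - 1)$$

`c` is the log of expected daily biomass (log g/day) at the covariate
origin; `log(λ)` is the annual trend per step of the year index, so
$1 - e^{\log\lambda}$ is the annual proportional decline; `v` is the
residual variance of daily log-biomass, and the daily variance is the
log-normal method-of-moments expression with log-location `y`. One
technical note: the equations use $e^y$ as the daily mean while the
variance formula corresponds to a log-normal with log-location $y$ (whose
mean would be $e^{y+v/2}$); no single log-normal satisfies both at once.
The package implements the expressions exactly as written, and the
synthetic generator and likelihood are consistent with each other.

The normal observation density admits negative catches with small
probability. The forward simulator clips such draws at zero and reports
the clipped fraction, while the fitting likelihood keeps the untruncated
normal — fidelity to the estimation model is preferred over internal
consistency of the simulator. At the default residual variance
`v = 0.870` and a mean exposure of 11.2 days the clipped fraction is
around 3%, which is why moment-validation tests use a smaller `v` where
clipping is negligible; the slight downward bias this induces in
recovered variance components on default-truth campaigns is visible (v
recovered around 0.81) but leaves the trend coefficient unbiased in our
recovery checks.

## Design matrix conventions

- **Day-of-year** uses January 1 = day 0 on a non-leap calendar. The
  projection window "1 April to 30 October" is days 90-302 inclusive.
- **Exposure endpoints are inclusive**: a one-day catch has τ₁ = τ₂ and
  length 1. Total exposure is Σ(τ₂ − τ₁ + 1).
- **Standardization.** Continuous covariates — day number, day number²
  (the square of the standardized day, standardized again), daily
  temperature/precipitation/wind, winter summaries, richness and
  Ellenberg means — are standardized to mean 0, sd 1 over the day rows of
  the fitting set; the year index, cluster dummies and land-use fractions
  (already in [0,1]) are exempt. Interaction columns are products of the
  post-standardization components. Projections re-apply the stored
  standardization record, never recompute it.
- **Year coding.** Default is the calendar offset (first study year = 1,
  gap years keep their spacing), so the trend is per calendar year. A
  consecutive coding over sampled years only is available
  (`year_coding = "consecutive"`); with gap years the two differ, and the
  calendar offset is the interpretation under which "annual decline"
  statements are meaningful.
- The seven named model variants differ only in which columns enter `X`;
  with the intercept they have 5 (null), 8 (basic), 13 (weather), 15
  (habitat), 12 (land use), 16 (land use + interactions) and 23 (final)
  location parameters.

## Priors, sampler, diagnostics

Priors are deliberately vague: Normal(0, sd = 1000) on every location
parameter and Uniform(0, 10) on the site sd and on √v. The bounds are
package choices (10 on a log-scale sd is far beyond any plausible value
for biomass data measured in grams per day).

The sampler is an adaptive Metropolis-within-Gibbs written for this
likelihood:

- Fixed effects are updated componentwise by random walks on an
  internally centered copy of the design (centering decorrelates the
  intercept from the year index and other non-centered columns; draws are
  reported back on the original scale). A joint proposal over all fixed
  effects with covariance learned during burn-in (Haario-style) handles
  the remaining correlation between the day, day² and year-interaction
  columns.
- Design columns that are constant in the data (e.g. a cluster dummy when
  no site of that cluster was drawn) do not enter the likelihood; their
  conditional posterior is the prior and they are sampled from it
  directly rather than by random walk.
- Site effects are proposed for all sites at once and accepted per site
  (the likelihood factorizes over sites); the site sd is updated by a
  log-scale random walk against the uniform prior; √v by a bounded random
  walk (cheap, because per-sample sums of `exp(η)` and `exp(2η)` are
  cached and `v` only rescales the variance).
- Proposal scales and the joint covariance adapt during burn-in only, so
  kept draws come from a fixed-kernel chain.

Defaults are a desk-scale protocol — 3 chains × 6000 iterations, 1000
burn-in, thinning 5 — which on a full-scale campaign (1500 catches, 17000
exposure days) runs in about 1.5 minutes and yields maximum Gelman-Rubin
statistics near 1.01-1.03; the published-scale protocol (3 × 24000, 4000
burn-in, thin 10) is one `mcmc_config()` call away. Convergence is
summarized by the classical (non-rank) potential scale reduction factor;
`fit_mcmc()` warns above 1.05 by default. Model comparison uses
`DIC = mean(D) + pD` with `pD = var(D)/2` (the convention of common Gibbs
front ends; the `mean(D) − D(posterior means)` variant is available), and
coefficient significance uses empirical two-sided posterior p-values
(`2·min(Pr>0, Pr<0)`, ties at zero counting to neither side).

## Projections

`project_season()` evaluates the fitted daily curve per posterior draw on
a day grid with covariates held at stated reference values.  Site random
effects are integrated out via the log-normal mean factor
$e^{\sigma^2_{site}/2}$ — the projection is a population-level seasonal
biomass, not a typical-site curve (a `u = 0` mode exists for site-level
displays). `weighted_decline()` forms, per draw, the ratio of summed
daily biomass over the window (seasonally weighted decline) or the ratio
at the peak day of the baseline year's posterior-mean curve (mid-summer
decline; the peak-day reading of "mid-summer" is a package decision —
month-specific averages can be formed from the projected series).
Intervals are 2.5/97.5% posterior quantiles of the per-draw declines.
When the specification has no year-by-day interactions the per-draw
weighted decline reduces exactly to $100(1 - e^{\log\lambda\,\Delta k})$,
which the tests assert to 1e-12. `counterfactual_no_trend()` zeroes the
trend coefficient and lets covariates follow their observed trajectories;
with a single changing covariate and no interactions it reduces to
`marginal_effect()`, i.e. $e^{\beta\,\Delta x}$.

## The synthetic campaign generator

`generate_dataset()` forward-simulates the full observation model so every
downstream stage can be tested against known truth. Its defaults emulate
the study conditions the model was built for: 63 sites giving 96
site-year combinations (37/20/5/1 sites sampled in 1/2/3/4 years),
habitat clusters drawn with probabilities 19/63, 41/63, 3/63, a March-
October season, site-year exposure windows averaging 176 days, and
emptying intervals with mean 11.2 and sd 6.3 days. Interval lengths
follow a normal truncated at one day whose parent parameters are
moment-matched so the truncated law keeps the configured mean and sd.
The default truth parameters are the published-scale posterior means
(intercept 2.450, trend −0.080, day −0.100, day² −0.447, temperature
0.304, precipitation −0.071, cluster offsets 0.420/0.332, year-by-day
interactions −0.003/0.010, site sd 0.334, v = 0.870).

Covariates are generated with *structure, not realism*: daily temperature,
precipitation and wind as seasonal sinusoids with AR(1) anomalies;
land-use fractions per site from a Dirichlet; richness and Ellenberg
values around cluster means. Consequently, passing recovery tests shows
the estimation machinery is correct under the model's own assumptions; it
does not show robustness to what real campaigns add — spatially correlated
trends between neighbouring sites, trap-level measurement drift,
phenological shifts, non-normal observation error, or covariates measured
with error. The generator also standardizes covariates exactly as the
fitting stage does, so recovered coefficients are directly comparable to
the truth.

## Weather, land use and habitat stages

Station weather series are decomposed as long-term trend + cyclic
seasonal profile + altitude effect + annual anomaly + residual. The
smooths are penalized splines (thin-plate over years, cyclic cubic over
day-of-year with the period pinned at 365) with GCV-selected penalties and
default basis dimensions 10 and 20 — the bases are named by family in the
source methods without dimensions, so the defaults are package choices.
The annual anomaly is implemented as per-year smooths of the daily
station-mean residuals; whether the anomaly should be smoothed or left as
raw daily means is an interpretation, flagged here, and the smooth reads
more naturally as a "seasonal component". Reconstruction is exact by
construction and asserted at every station-day.

Residuals get a separable exponential(space) × exponential(time)
covariance — the simplest valid spatio-temporal family, chosen because the
source names none — fitted by weighted least squares to a binned empirical
variogram of sampled residual pairs. Interpolation to trap locations is
*ordinary* (not simple) kriging of same-day residuals under the fitted
spatial covariance plus the deterministic components at the target:
ordinary kriging keeps unbiasedness without assuming the residual mean is
known, and with a zero nugget it is exact at station locations (asserted).
Stations beyond 100 km are excluded; a day with no station inside the
radius is an error. Distances are great-circle (haversine) kilometres. A
frost day is a day with *mean* temperature strictly below 0 °C (the
min-vs-mean choice is unstated in the source; the strict inequality means
an exact 0 °C day is not frost), counted over 1 November - 28/29 February
(the package uses the non-leap 120-day window) preceding the season.

Land-cover fractions surveyed at two epochs are interpolated on the logit
scale, linearly in year — exactly the prediction of a saturated two-point
binomial-logit GLM, which the tests use as an oracle; a dispersion
parameter has no effect on a saturated two-point fit, which is why the
closed form is the implementation. Fractions of exactly 0 or 1 are
shrunk by 1/(2·1000) before the logit. The "other" cover category is the
omitted reference, so the four modelled fractions need not sum to one.
Richness trends are Poisson mixed models with a site random intercept
(Laplace approximation via `lme4`); the residual-deviance/df dispersion is
reported and flagged above 1.5, since herb richness in data of this kind
is overdispersed and a Poisson fit then understates the slope's standard
error (a negative-binomial variant is out of scope by design).

## Numerical choices and degenerate inputs

- Likelihood evaluations fail loudly (naming the sample) on non-finite
  densities; `v = 0` makes every sample variance zero and is rejected at
  the likelihood, though the generator accepts it for noise-free checks.
- All-zero weather residuals yield a flagged degenerate covariance model
  (sill 0) under which kriging falls back to the residual mean.
- A window shorter than one emptying interval yields a single catch
  covering the window; the final interval of a season is cut at the
  window end.
- Constant richness counts return a zero slope directly (the mixed model
  is degenerate there); constant design columns are prior-sampled as
  described above.
- Every randomized entry point (generator, sampler, CLI) requires an
  explicit integer seed and is bit-reproducible given one; chains use
  fixed offsets from the configured seed.

## Problem sizes used by the test suite

The suite exercises full-scale recovery once (63 sites / 96 site-years,
desk-scale MCMC protocol, a few minutes) and runs the remaining recovery,
coverage and comparison properties on smaller campaigns chosen for
identifiability rather than realism: 10-20 sites over 6-10 years with
several sites per habitat cluster, and 20 seeded replicates at 12 sites ×
6 years for the credible-interval coverage of the trend (coverage is a
scale-free property, so the reduced size changes power, not validity).
The convergence fixture uses 20 sites with cluster probabilities
0.4/0.4/0.2 so that all dummies are informed by data.

## Known limitations

- The observation density is an untruncated normal; for short exposures
  or very large `v` its negative-mass probability is not negligible, and
  fitted variance components absorb the simulator's clipping.
- No spatial correlation between sites beyond the random intercept, and
  no propagation of weather-interpolation uncertainty into the biomass
  model (by design, matching the estimation procedure the package
  implements).
- DIC with `pD = var(D)/2` is noisy for short chains; compare models with
  the same protocol and seeds, and prefer longer runs for close calls.
- The mid-summer decline is defined at the baseline year's peak day;
  under strong seasonal-shape change the choice of definition matters and
  both the peak-day and window-weighted quantities should be reported.
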