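---
title: "Stream thermal regimes under riparian thinning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stream thermal regimes under riparian thinning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamtherm)
```

## The problem

Thinning second-growth riparian forests is an attractive restoration tool,
but removing canopy over small streams reduces shade, admits solar
radiation, and can warm the water — a regulated quantity where cold-water
fishes and amphibians live. The natural experimental design for measuring
that impact is Before-After-Control-Impact (BACI): each treated (thinned)
reach is paired with an upstream reference reach and a downstream reach,
monitored in one pre-treatment and one post-treatment water year, and the
treatment effect is the *double difference*

\[
\Delta_{\mathrm{BACI}} =
(\bar T_{\mathrm{treated,post}} - \bar T_{\mathrm{treated,pre}}) -
(\bar T_{\mathrm{upstream,post}} - \bar T_{\mathrm{upstream,pre}}),
\]

which cancels both site-to-site differences and year-to-year weather.

`streamtherm` implements the full analysis chain for such a study —
hourly logger QA, thermal-regime descriptors, heteroscedastic BACI mixed
models, zero-anchored longitudinal profiles, multivariate regime-structure
tests, and AICc covariate screening — together with a synthetic-study
generator with known injected effects, so every estimator can be validated
against ground truth.

## Thermal-regime descriptors

Hourly temperatures are first collapsed to daily summaries (maximum,
minimum, mean, range, and within-day sample variance of the hourly values).
A day qualifies when at least 90 % of its 24 hours are present; incomplete
days are kept but excluded from seasonal statistics. Seasons partition the
water year (labelled by its ending calendar year, Oct 1 – Sep 30): Fall
(Oct–Dec), Winter (Jan–Mar), Spring (Apr–Jun), Summer (Jul–Sep).

Per (site, reach, water year, season) the package computes fourteen
descriptors: six of magnitude (average daily maximum, MWMT, average daily
mean, MWAT, cumulative degree days, average daily minimum), four of
variability (average/maximum daily range, average/maximum within-day
variance), and four of frequency/duration (days and maximum consecutive
days with daily maxima above 16 °C and 20 °C).

Choices the descriptor definitions required:

* **MWMT/MWAT windows** are means over 7 consecutive calendar days lying
  fully inside the season; a window containing an absent or non-qualifying
  day is skipped. No cross-season windows: the descriptors are seasonal
  summaries.
* **Threshold descriptors** compare the daily *maximum* to 16/20 °C —
  these thresholds are regulatory cold-water criteria, conventionally
  applied to maxima; the statistic is configurable to the daily mean.
* **"Variance"** is the within-day sample variance (n − 1) of hourly
  values, summarized seasonally by its mean and maximum. A weekly-window
  alternative would also be defensible; the within-day definition is the
  one that responds directly to diel amplitude, which is what canopy
  removal perturbs.
* **Degree days** use base 0 °C (a plain cumulative sum of daily means).
* **Reach-level series** use the sensor at the reach's *downstream* extent
  (`reach_bottom`), which integrates thermal exposure over the whole reach;
  `reach_top` is available by argument.
* A season is flagged *low coverage* when fewer than 80 % of its days
  qualify.

Every windowed or run-length statistic is verified in the test suite
against an independent brute-force oracle (exhaustive 7-day window scans,
explicit run scans, naive summation) on a thousand randomized seasons.

## The BACI mixed model

For one response descriptor in one season, with one value per
(site *s*, reach *r*, year *y*):

\[
T_{sry} = \mu + \alpha_r + \beta_y + (\alpha\beta)_{ry} + b_s +
\varepsilon_{sry}, \qquad
b_s \sim N(0, \sigma^2_{\mathrm{site}}), \quad
\varepsilon_{sry} \sim N(0, \sigma^2_{g(r,y)}).
\]

Reference levels are the upstream reach and the pre-treatment year, so the
interaction coefficients *are* the thinned and downstream BACI differences.
Residual variances differ by stratum; the default strata are the six
Reach × Year cells — the most general reading of "variance relaxed among
reaches and years" — with Reach-only, Year-only, and homoscedastic options.

`baci_lmm()` maximizes the marginal Gaussian likelihood (ML or REML)
directly: fixed effects are profiled out by generalized least squares, and
the variance parameters are optimized on the log-SD scale with `nlminb`
(relative tolerance 1e-8, box bounds on log SDs, three perturbed restarts
on non-convergence, best point kept with a flag). Because every site block
in a balanced design shares the same 6 × 6 covariance, the likelihood is
evaluated from pre-computed cross-products — one small Cholesky per
distinct stratum pattern per evaluation — which makes thousand-replicate
calibration studies cheap. A relative ridge of 1e-10 on the block diagonal
keeps the factorization stable when stratum variances collapse toward zero
while the site variance does not (noiseless or near-noiseless responses).
The test suite checks the fixed effects, variance components and ML
log-likelihood against `nlme::lme` with `varIdent` weights, and against
ordinary least squares in the homoscedastic zero-site-variance case.

**Wald intervals** use the contrast standard error from
\((X'V^{-1}X)^{-1}\) on a *t* reference with
\(n - p - n_{\mathrm{sites}} + 1\) degrees of freedom (45 for ten complete
sites) — a deliberately small-sample-conservative reference for designs of
this size. Under the null, with ten sites and heteroscedastic strata, the
measured rejection rate is ≈ 0.06 over a thousand simulated studies.

**Cluster-bootstrap intervals** resample whole sites with replacement —
the site is the independent replicate — and recompute the plug-in double
difference of resampled cell means per replicate (2000 by default),
reporting the percentile interval. Percentile intervals of a cluster-level
mean are known to be anti-conservative at ten clusters (the interval is
effectively a z-interval with an n-divisor SD); the package reports the
method honestly rather than substituting a different interval, and the
calibration section of the test suite records the measured rate.

**Residual diagnostics** assess normality on conditional residuals
(marginal residuals minus the site-intercept BLUPs). Within each stratum
the residuals are externally studentized — each value scaled by the
leave-one-out SD of its stratum, so an outlier cannot mask itself by
inflating its own scale estimate — and mapped through the *t* CDF to
normal quantiles before a Shapiro–Wilk test. Measured over a hundred
simulated studies, Gaussian residuals are rejected 9 % of the time while
heavy-tailed (t with 2 df) residuals are detected 75 % of the time. A
rejection (or a degenerate, zero-variance fit) makes the pipeline switch
that contrast to the bootstrap interval.

When a season has no pre-treatment data at all (sensors deployed in the
spring of the pre-treatment year, as can happen in a staggered roll-out),
the BACI difference is not estimable; `baci_table()` then reports the
post-treatment difference between treated and upstream reach means across
sites, flagged `post_only`.

## Longitudinal profiles

For each site and season the change (post − pre) in a descriptor (MWMT by
default) is computed at every sensor along the channel and anchored by
subtracting the change at the upstream-most sensor, so every profile starts
at exactly zero and sites are directly comparable. Sensors sit at the four
reach boundaries and are shared between adjacent reaches (the bottom of one
reach is the top of the next).

The qualitative downstream outcomes get a quantitative rule
(`classify_trajectory()`): *undetectable* if no anchored change exceeds
0.2 °C in magnitude; *persists* if the value at the downstream extent
retains at least 50 % of the peak change; *dissipates* otherwise. Both the
tolerance and the persistence fraction are arguments — the rule quantifies
a description, it is not itself an estimate.

## Multivariate regime structure

The descriptor matrix has one row per retained (site, reach, year, season)
combination and one column per selected descriptor (the fourteen above by
default; the list is an argument). Columns are z-standardized before
Euclidean distances are computed: the descriptors mix °C, °C², and day
counts, and raw Euclidean distance would be dominated by whichever column
has the largest units. Raw mode is available. Columns that are constant in
the analyzed subset (e.g. no day anywhere above 20 °C) cannot be
standardized and are dropped with a warning; rows with unavailable
descriptors are dropped with a reported count.

Non-metric multidimensional scaling is run in two dimensions on the
Euclidean distances via `vegan::monoMDS` (Kruskal stress-1, monotone
regression). The first start is the metric principal-coordinates
configuration, followed by random restarts under a seed — up to 999, the
iterative-optimization budget, stopping early once two solutions agree
within 1e-4 stress. Starting from the metric configuration guarantees the
reported stress never exceeds the metric-MDS stress on the same distances,
which the test suite verifies against an independent isotonic-regression
stress oracle. Reach groups get 95 % normal-theory ellipses (mean,
covariance, chi-square radius); groups with fewer than three points are
skipped, collinear groups flagged degenerate.

PerMANOVA partitions the squared Euclidean distances by
Reach + Year + Reach:Year (`vegan::adonis2`, sequential sums of squares)
with permutation p-values, \(p = (\#\{F^* \ge F\} + 1)/(n_{\mathrm{perm}}
+ 1)\), 999 permutations by default. Rows are permuted freely — the
convention of common PerMANOVA implementations and the scheme under which
the interaction test is exact for exchangeable rows; a restricted
within-site scheme is available and is the more conservative choice when
site effects are strong. Sites appear in several rows (reaches pseudo-
replicate sites); that is a property of the design this analysis mirrors,
not an oversight.

## Covariate screening and model selection

Candidate fixed-effect models for a summer descriptor are screened in the
standard information-theoretic workflow: a Pearson correlation matrix over
covariates (shade, light, upstream temperature, air temperature, proximity
to upstream treatment, and physical site characteristics), rejection of
candidate sets containing a pair with |r| > 0.6, VIF checks
(\(1/(1-R^2_j)\)), then AICc ranking,

\[
\mathrm{AICc} = -2\log L + 2k + \frac{2k(k+1)}{n-k-1},
\]

with all candidates fit by Maximum Likelihood with a random site intercept
(`nlme::lme`), and the best-supported model refit with REML for reported
coefficients. The parameter count *k* is the number of fixed-effect
coefficients plus two variance components; since the random structure is
shared, the "+2" is a common constant and cannot reorder candidates. *n*
is the number of response rows, acknowledging the design's
pseudo-replication. Ties within 1e-6 AICc go to the smaller model. The
exact a priori candidate sets of any particular field study are a
configuration input, not package constants; the null (intercept) and the
categorical BACI Reach × Year model can both enter the set, which lets the
workflow reproduce the two signature outcomes — continuous shade/upstream
covariates outranking the categorical BACI model where effects are strong,
and the null model winning where there is little variation to explain.

## The synthetic-study generator

`synth_study()` emulates the design the pipeline targets: 10 sites in
three watersheds (5 + 3 + 2), three ~150–200 m reaches per site with
sensors at the four shared reach boundaries, hourly water temperatures over
one pre- and one post-treatment water year (2016 and 2018; the intervening
year is the treatment year), mid-summer hemispherical-photo records (10–22
per reach-year) and four paired pyranometer records per reach.

The temperature model is

* an annual sinusoid peaking mid-August (defaults: mean 10.5 °C, amplitude
  3.5 °C — a small coastal stream under maritime climate),
* a diel sinusoid peaking at 15:00 whose amplitude (summer default 1.5 °C
  peak-to-trough) is damped toward winter, as under heavy canopy and
  winter cloud,
* hourly AR(1) noise shared along a site's sensors (coefficient 0.7,
  innovation SD 0.3 °C) plus small sensor-specific white noise (0.05 °C) —
  the shared component encodes the longitudinal connectivity of sensors in
  the same channel,
* site intercepts with SD 1 °C.

The treatment perturbation is added in the post-treatment year at the
thinned-reach sensor as a daylight *plateau*: unit weight 10:00–20:00 with
half-height shoulders at 09:00/21:00, zero at night, scaled by the site's
realized effect (mean `effect_dmax_C`, default 2.8 °C; between-site SD
1 °C, which reproduces field-scale confidence-interval widths) and by a
seasonal weight (Summer 1, Spring 0.6, Fall 0.35, Winter 0 — the seasonal
ordering observed for maximum-temperature responses). The plateau shape is
deliberate: the defining contract of the generator is that *daily maxima
rise by exactly the injected amount in expectation*. A peaked (half-sine)
perturbation under-delivers whenever hourly noise shifts the time of the
daily maximum off the peak — measured at about −0.25 °C under the default
noise — whereas a plateau covering the plausible daily-maximum hours has
measured bias below 0.01 °C, while pre-dawn minima stay untouched and
daily range and variance rise. The downstream-reach sensor receives a
configurable fraction (default 0.5) of the same perturbation.

Shade records draw VisSky and GSF from beta distributions around reach
means (pre-treatment closure 95 %, effective shade 93 %; thinned-reach
post-treatment losses 17 and 23 percentage points); light records pair a
daylight irradiance bell above the canopy with below-canopy values at a
beta-distributed transmission (pre 6 %, thinned post +27 points).
Generation is fully deterministic given the config seed.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about field data: no discharge or hydrology (no
low-flow amplification of sensitivity), no energy-balance physics linking
shade loss to warming (the temperature and shade effects are injected
independently), no day-to-day weather autocorrelation beyond the hourly
AR(1), no sensor drift or fouling, no canopy regrowth between
post-treatment years, and no spatial decay of the downstream effect within
a reach (the persistence fraction applies at the boundary sensor). The
generator validates the *estimators*, not the ecology.

## Validation design and problem sizes

The acceptance layer of the test suite runs, as the package's chosen
validation scale: descriptor-oracle agreement on 1,000 randomized seasons;
parameter recovery over 200 full synthetic studies (mean recovered thinned
effect within ±0.1 °C of the injected 2.8 °C, downstream/thinned ratio
within ±0.1 of 0.5); type-I error of the Wald and bootstrap BACI tests
over 1,000 null response-level studies and PerMANOVA p-value uniformity
over 500 null data sets; NMS-versus-metric-MDS stress dominance on 20
random matrices; and one end-to-end study checking the qualitative
signature (summer thinned > summer downstream > winter ≈ 0, minima
unchanged, anchored profiles starting at zero) plus 20 minimal-effect
two-site studies expected to yield no significant BACI differences.

## Known limitations

* The Wald *t* reference df and the bootstrap flavour are conventions, not
  derivations; at ten sites the percentile cluster bootstrap rejects a
  true null noticeably more than 5 % of the time (see the calibration
  discussion above). Users who need strict nominal coverage at this scale
  should rely on the Wald interval.
* With two sites (a minimal watershed), the six stratum variances are
  estimated from two observations each; the fit is reported but intervals
  are wide and the diagnostics uninformative.
* Ordination and PerMANOVA treat rows as exchangeable; with strong site
  effects the free-permutation p-values are liberal. The within-site
  permutation option is the conservative alternative.
* The generator's parameters are descriptive choices, not estimates fit to
  any particular stream.
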