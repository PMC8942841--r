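---
title: "Methods: temperature variability as a modifier of heat-mortality risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature variability as a modifier of heat-mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvheat)
```

## The scientific question

Day-to-day temperature variability (TV) and heat are distinct exposures: a
day with mean 15 °C can arise from a 13-17 °C swing or a 5-25 °C swing, and
the physiological stress differs. `tvheat` implements a two-stage
time-series analysis of whether short-term TV *modifies* the
heat-mortality association in the warm season, and how much of the
heat-attributable mortality burden accrues under each TV regime.

## Exposure definitions

**TV.** TV on day $t$ is the sample standard deviation of the pooled daily
minimum and maximum temperatures over the current day and the preceding
$w$ days (default $w = 1$, i.e. the four values
$T^{min}_t, T^{max}_t, T^{min}_{t-1}, T^{max}_{t-1}$; sensitivity runs use
$w = 2, 3$). The sample divisor $2(w+1)-1$ is used. TV is missing whenever
any constituent temperature is missing.

**TV quartiles.** Stratification is *relative*: cutpoints are the
25th/50th/75th percentiles (linear interpolation between order statistics,
`quantile` type 7) of the location's own warm-season TV distribution, so a
"high-TV day" in a maritime climate and in a continental climate are both
defined against local experience. Intervals are right-closed (ties go to
the lower quartile). Whether cutpoints should come from warm-season days
only or all days is not identifiable from the analysis description we
follow; warm-season days are used because the model is fitted on them.

**Warm season.** The $n$ consecutive calendar months (default 4, possibly
wrapping December to January) maximizing the long-run mean of daily mean
temperature; ties break to the earliest calendar start.

## Stage 1: location-specific quasi-Poisson DLNM

For each location, on warm-season days,

$$E(Y_t) = \exp\big(\alpha + \beta\,TV_t + cb(T, lag)_t +
  cb(T, lag)_t \times \mathbf{1}[Q_{TV}(t) = q] +
  ns(time_t) + \gamma\,DOW_t\big), \qquad \mathrm{Var}(Y_t) = \theta \mu_t$$

* The cross-basis $cb$ is the tensor product of a natural cubic spline of
  daily mean temperature (interior knots at the 50th/90th percentiles of
  the location's warm-season distribution, boundary knots at its range,
  no intercept; dimension 3) and a natural cubic spline of lag over
  0-10 days (two interior knots equally spaced on the log-lag scale,
  $10^{1/3}$ and $10^{2/3}$, anchored at lag 1 because $\log 0$ is
  undefined; with intercept; dimension 4). Column $(j,k)$ of the
  cross-basis at day $t$ is $\sum_{l=0}^{L} B_j(T_{t-l})\,C_k(l)$.
* The interaction dummies use the TV quartile of the cross-basis row's
  own day $t$ (the model multiplies $cb$ at day $t$ by the quartile at
  day $t$), with Q1 as reference, so the main-effect block is the Q1
  surface and the three interaction blocks are Q2-Q1, Q3-Q1, Q4-Q1
  contrasts.
* Seasonality and trend are absorbed by a natural spline of calendar time
  with $\mathrm{round}(4 \times \text{years spanned by the used days})$
  df; day-of-week enters as six treatment contrasts against Monday;
  relative humidity, when enabled, as a natural spline with 3 df.
* Estimation is Poisson IRLS (`glm.fit`, relative deviance tolerance
  1e-8, 50 iterations); quasi-Poisson point estimates coincide with
  Poisson ML, and the dispersion $\theta$ = Pearson $\chi^2$ / residual
  df rescales the covariance. No floor is applied at $\theta = 1$.
  Rows with any missing outcome or covariate are dropped (complete-case;
  spline imputation of temperature series is an opt-in sensitivity
  path). Locations spanning fewer than two years of usable warm-season
  data, rank-deficient designs, and non-converged fits are dropped with
  a recorded reason.

**Reduction.** The coefficients of each quartile's surface are collapsed
to the *overall cumulative* association on the temperature basis:
reduced coefficient $j$ is $\sum_k \hat\eta_{jk} \sum_l C_k(l)$, the
lag-summed risk of sustained exposure at a given temperature. The full
fit covariance is pushed through the same linear map, *including the
cross-quartile blocks* - the downstream curve-difference tests need the
correlation induced by the shared sample.

## Stage 2: pooling, curve tests, TVST

**Pooling.** The stacked per-location vector of four reduced quartile
curves (12 coefficients) is pooled by multivariate random-effects
meta-analysis: $y_i \sim N(X_i\beta,\ S_i + \Psi)$, maximized by REML
with $\Psi$ parameterized to stay positive semi-definite. With outcomes
of dimension 12 pooled over tens of locations an unstructured $\Psi$ (78
parameters) is not estimable, so the default structure is diagonal; the
unstructured Cholesky parameterization is available for low-dimensional
use. Optimization is quasi-Newton (BFGS) on the profiled restricted
likelihood (the fixed effects are profiled out in closed form at each
$\Psi$). With a single location the fit degenerates to that location's
estimate with $\Psi = 0$; with $\Psi$ fixed at zero it reproduces the
fixed-effects inverse-variance estimate, a consistency identity the test
suite checks. Location-level meta-predictors (entered one at a time, as
in the sensitivity analyses) extend the fixed design to
$X_i = [I, u_i I]$.

**BLUPs.** Each location's curve set is shrunk toward the pool,
$\hat y_i^{BLUP} = X_i\hat\beta + \Psi(S_i + \Psi)^{-1}(y_i - X_i\hat\beta)$,
with a covariance combining the conditional random-effect variance and
the uncertainty of $\hat\beta$. BLUP curves drive attribution, which is
how locations with few daily deaths borrow strength.

**Curve-difference test.** The repeated-measures test pools the stacked
4-quartile outcome (carrying the within-location cross-quartile
covariance) and Wald-tests the joint nullity of the three contrast
blocks; df $= 3 \times 3$.

**Pointwise test and TVST.** In each country, at a temperature
percentile $p$, every location contributes its Q4-Q1 cumulative log-RR
difference at its own $p$-th warm-season temperature (relative to a
common reference percentile, default the 50th, which lies below the heat
range so the contrast there is null under a threshold-type effect), with
a delta-method variance. Differences are pooled by *fixed-effects*
inverse-variance weighting - the quartile estimates come from the same
sample, so between-location heterogeneity is not re-estimated here - and
z-tested. The TV-sensitive heat threshold (TVST) is the smallest grid
percentile from which the test rejects at every grid point up to the
100th (integer grid from the pooled MMT percentile; the grid and the
run-of-rejections rule are documented operationalizations - the source
analysis reports percentile thresholds without stating its grid).
Countries without an identifiable TVST receive the arithmetic mean of
the identified TVST percentiles.

## MMT, attribution, Monte Carlo intervals

**MMT.** The minimum mortality temperature is the argmin of the pooled
cumulative log-RR over a 0.1 °C grid restricted to the 1st-99th
percentiles of the warm-season temperature distribution (the extremes
are excluded as unstable; ties go to the lowest temperature). MMTs are
quartile-specific by default (a common-MMT mode is available by
configuration); curves are re-centred at the MMT post hoc, which is
exact because centering only shifts the curve.

**Attributable burden.** The backward attributable-risk perspective is
used: a day's deaths are attributed to its own exposure history through
the cumulative RR, $AN_t = Y_t\,(1 - 1/RR_q(T_t))$ for warm-season days
in quartile $q$ with $T_t$ above the MMT, summed over days. The burden
splits at the TVST into the components (MMT, TVST] and (TVST, ∞).
Attributable fractions are reported on two denominators: `af` divides by
all warm-season deaths (so component AFs add up to the quartile's total
heat AF), and `af_in_component` divides by the deaths on the component's
own qualifying days (the scale on which the above-TVST burden visibly
dominates the between-component burden). Both are carried because the
two conventions answer different questions - share of the total burden
versus intensity within the band.

**Empirical CIs.** Coefficient vectors are drawn from the multivariate
normal at the BLUP mean and covariance (Monte Carlo, default 1,000
draws; MMT and TVST held fixed across draws), the whole attribution is
recomputed per draw, and the 2.5th/97.5th percentiles of the draws give
the interval. Aggregation to country/region/global sums attributable
numbers *draw by draw* (draws aligned by index), so aggregated intervals
respect the within-draw dependence. Per-location draw seeds derive from
the master seed by a fixed offset, making runs reproducible and
parallelizable.

## The synthetic-data generator

Ground truth is supplied by a generator whose defaults define the
package's reference study conditions: 20 locations, 5 years each, ~30
baseline deaths/day, an annual temperature sinusoid (mean 15 °C,
amplitude 10 °C) plus AR(1) noise (autocorrelation 0.7, innovation SD
2 °C), a positive diurnal range (mean 8 °C, SD 2 °C) generating
tmin/tmax around tmean, mild winter-peaked baseline seasonality (15%),
weekend effects, and overdispersion θ = 1.2. The heat effect is a
hockey-stick log-RR above the location's 75th warm-season percentile
with per-quartile slopes (0.02, 0.045, 0.075, 0.11) per °C - a monotone
TV modification whose top-quartile effect reaches a relative risk near
1.5 at typical extreme exceedances, comparable to published warm-season
heat effects. Lag weights decay geometrically (ratio 0.6, truncated at
lag 10, normalized): the real lag surface is data-estimated, so the
simulation needs one concrete, documented truth. The modification is
injected through the quartile of the simulation's *own* TV statistic
(window 1, warm-season-relative cutpoints), so the pipeline's exposure
definition and the truth coincide and parameter recovery is well-posed.
Missingness, when requested, is injected completely at random after
generation.

What the generator does *not* emulate: spatial correlation between
locations, weather-reanalysis realism, demographic structure,
cause-of-death mixtures, harvesting/displacement dynamics, or
between-location heterogeneity in the true slopes. Passing recovery
tests therefore demonstrates that the pipeline estimates what it claims
under a known data-generating process of the assumed form - not that
real mortality data satisfy that form.

## Numerical and design choices

* **Spline primitive:** `splines::ns` throughout; the temperature basis
  has no intercept (the model supplies one), the lag basis does - the
  standard identification of the tensor-product cross-basis.
* **Percentile convention:** linear interpolation between order
  statistics everywhere (quartile cutpoints, knot placement, MMT ranges,
  TVST mapping), so every test oracle can reproduce the value.
* **Spline interpolation of gaps** (sensitivity path) uses a natural
  cubic interpolating spline through the observed points; leading or
  trailing gaps are refused rather than extrapolated, and observed
  entries are never altered. The spline order is not stated in the
  analysis we follow; natural cubic is our documented choice.
* **Same-day TV in the linear term:** the model's linear TV term uses
  the day's own TV, as written in the model equation, not a lag-window
  average.
* **Degenerate pointwise contrasts:** when the evaluation percentile
  coincides with the reference percentile, the Q4-Q1 contrast is
  structurally zero and the test reports p = 1; the zero-variance error
  is reserved for genuinely degenerate covariances.
* **Dispersion:** may fall below 1; no truncation is applied.
* **Ties:** MMT argmin ties resolve to the lowest temperature; warm
  season ties to the earliest start month; quartile boundary ties to the
  lower quartile.

## Validation design and problem sizes

The acceptance suite exercises: exact oracle equivalence of the
cross-basis and its reduction (brute-force loops, 15-day series);
natural-spline parameterization invariance against an independent
truncated-power construction; closed-form log-lag knots; coverage of an
injected Q4-only contrast (100 replicates of a 5-year location); size of
the curve-difference and pointwise tests under null modification (200
replicates of 10 locations × 3 years - scaled-down studies chosen so the
full calibration runs at desk scale); end-to-end recovery of the
monotone AF signature (20 replicates of the 20-location default
scenario); a spreadsheet oracle for attributable numbers; Monte Carlo
interval coverage (500 single-location replicates at 100 draws, with the
attribution reference held at the 25th warm-season percentile - inside
the flat region of the true curve - so the experiment isolates the
interval machinery from the argmin selection effect, which would
otherwise bias every relative risk upward at a single noisy location);
REML recovery of a known between-study variance; and configuration-only
sensitivity switching with manifest-digest localization of what changed.

## Known limitations

* The natural-spline basis cannot represent the hockey-stick truth
  exactly; near the kink the fitted curve smooths the corner, which is
  why attribution references in validation sit in the flat region and
  why contrasts are evaluated a few degrees above the threshold.
* The diagonal between-location covariance in the repeated-measures test
  trades efficiency for estimability at small numbers of locations.
* TVST detection inherits the power of the country-level pointwise test;
  with few locations per country thresholds are often unidentified and
  fall back to the cross-country mean.
* Monte Carlo intervals propagate coefficient uncertainty only; MMT and
  TVST are treated as fixed, as in the analysis this package follows.
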