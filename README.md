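# tvheat

Does short-term **temperature variability (TV)** modify the
heat–mortality association? Two days with the same mean temperature can
come from very different swings (13–17 °C versus 5–25 °C), and the
mortality burden of heat may differ between stable and fluctuating
weather. `tvheat` implements the full two-stage time-series pipeline
used to answer this question on multi-location daily mortality data, and
ships a ground-truth synthetic data generator so every stage is testable
end to end. It is aimed at environmental epidemiologists working with
daily death counts and weather series.

## The method

**Exposure.** TV on day *t* is the sample SD of the pooled daily minimum
and maximum temperatures over the current and preceding *w* days
(default *w* = 1, i.e. four values; 0–2 and 0–3 windows as sensitivity).
Days are stratified into quartiles Q1–Q4 of the location's own
warm-season TV distribution (the warm season = the warmest 4 consecutive
calendar months).

**Stage 1** fits, per location on warm-season days, a quasi-Poisson
regression with a DLNM cross-basis × TV-quartile interaction:

```
E(Y_t) = exp( α + β·TV_t + cb(T, lag 0–10) + cb(T, lag 0–10) × Quartile_TV(t)
              + ns(time, 4 df/year) + γ·DOW_t ),        Var(Y_t) = θ·μ_t
```

where `cb` is the tensor product of a natural cubic spline of daily mean
temperature (knots at the warm-season 50th/90th percentiles) and a
natural cubic spline of lag (2 knots log-spaced over 0–10 days). Each
quartile's coefficients are reduced to the overall cumulative
exposure–response curve with full covariance (including cross-quartile
blocks).

**Stage 2** pools the stacked quartile curves across locations by
multivariate random-effects meta-analysis (REML) at the country,
regional and global levels, computes BLUPs per location, Wald-tests the
joint difference of the four curves (repeated-measures structure), and
in each country scans temperature percentiles with a fixed-effects
Q4-vs-Q1 contrast to find the **TV-sensitive heat threshold (TVST)** —
the percentile above which the TV modification is significant.

**Attribution.** Relative risks are referenced to the minimum mortality
temperature (MMT) of the pooled curves; attributable deaths are computed
backward per day, `AN_t = Y_t (1 − 1/RR_q(T_t))`, summed, decomposed at
the TVST into (MMT, TVST] and (TVST, ∞) components, and equipped with
Monte Carlo empirical CIs (default 1,000 coefficient draws).

See `vignettes/tv-heat-methods.Rmd` for assumptions, numerical choices
and limitations.

## Worked example

```r
library(tvheat)
scenario <- sim_scenario(n_locations = 8, seed = 1)   # synthetic study, known truth
run <- run_pipeline(default_config(mc_draws = 200, seed = 1), scenario)

subset(run$attribution$global$table, component == "total",
       select = c(quartile, an, af, af_lo, af_hi))
#>  quartile        an        af     af_lo     af_hi
#>        Q1  622.6713 0.4662318 0.2500945 0.6871772
#>        Q2  705.9631 0.5285975 0.4591920 0.6090883
#>        Q3 1391.9211 1.0422159 0.8534098 1.2049259
#>        Q4 1819.0546 1.3620368 1.1862856 1.5368883

run$quartile_test[c("statistic", "df", "p_value")]
#> X2 = 57.0 on 9 df, p = 5.05e-09

run$tvst
#>  country_id identified tvst_percentile own_percentile
#>   country01       TRUE        95.00000             95
#>   country02       TRUE        90.00000             90
#>   country03       TRUE        89.00000             89
#>   country04      FALSE        91.33333             NA
```

Reading the output: the generator injects monotone heat slopes across TV
quartiles; the pooled attributable fraction of warm-season deaths rises
from 0.47% (Q1) to 1.36% (Q4), the four exposure–response curves differ
(Wald χ² = 57.0, 9 df), and three of four synthetic countries show an
identifiable TVST around the 90th temperature percentile — the fourth
receives the mean of the identified thresholds. `write_run_tables(run, dir)`
exports `curves.csv` (level, quartile, percentile, temp, rr, lo, hi),
`tvst.csv` (country_id, identified, tvst_percentile, own_percentile) and
`attribution.csv` (scope, group, quartile, component, an, an_lo, an_hi,
af, af_lo, af_hi, component_deaths, af_in_component). A thin CLI with
`simulate` and `run` subcommands lives at `inst/cli/tvmod.R`; the run
configuration can be supplied as a YAML file mirroring
`default_config()`.

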