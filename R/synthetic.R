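#' Simulation scenario for synthetic multi-location studies
#'
#' Defines the data-generating process used for ground-truth validation:
#' daily mean temperature as an annual sinusoid plus AR(1) noise, tmin
#' and tmax generated around tmean from a positive diurnal range, an
#' overdispersed count process whose log mean adds a seasonal baseline,
#' day-of-week factors, and a distributed-lag heat effect. The heat
#' effect is a hockey-stick log-RR: zero below the location's threshold
#' (a quantile of its warm-season tmean) and linear above, with slope
#' depending on the day's TV quartile - quartiles of the simulation's own
#' TV statistic, so the pipeline's exposure definition and the injected
#' truth coincide. Lag weights decay geometrically (ratio 0.6, truncated
#' at `lag_max`, normalized to sum 1).
#'
#' @param n_locations number of locations.
#' @param years length of each series in years.
#' @param baseline_deaths expected daily deaths at reference.
#' @param seasonal_amplitude_deaths relative amplitude of the winter-peak
#'   baseline seasonality (0 = none).
#' @param temp_mean_annual annual mean temperature, degrees C.
#' @param temp_seasonal_amplitude seasonal half-range, degrees C.
#' @param temp_ar1 lag-1 autocorrelation of the residual process, in
#'   (-1, 1).
#' @param temp_daily_sd innovation SD of the AR(1) residuals, degrees C
#'   (controls TV).
#' @param diurnal_range_mean,diurnal_range_sd mean and SD of the daily
#'   diurnal range (tmax - tmin), degrees C.
#' @param heat_log_rr_per_degree length-4 vector: log-RR per degree C
#'   above the threshold for TV quartiles Q1..Q4 (the injected
#'   modification).
#' @param heat_threshold_quantile quantile of warm-season tmean defining
#'   the location's true heat threshold.
#' @param dow_effects 7 multiplicative day-of-week factors (Mon..Sun).
#' @param overdispersion variance/mean ratio theta >= 1; 1 gives Poisson.
#' @param hemisphere "north" or "south" (sets the seasonal peak).
#' @param missing_rate MCAR missingness fraction in [0, 1).
#' @param lag_max maximum lag of the injected effect.
#' @param lag_decay geometric decay ratio of the true lag weights.
#' @param locations_per_country,countries_per_region grouping structure.
#' @param seed master seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_locations = 20L, years = 5L,
                         baseline_deaths = 30,
                         seasonal_amplitude_deaths = 0.15,
                         temp_mean_annual = 15,
                         temp_seasonal_amplitude = 10,
                         temp_ar1 = 0.7, temp_daily_sd = 2,
                         diurnal_range_mean = 8, diurnal_range_sd = 2,
                         heat_log_rr_per_degree = c(0.02, 0.045, 0.075, 0.11),
                         heat_threshold_quantile = 0.75,
                         dow_effects = c(1, 1, 1, 1, 1, 1.03, 1.05),
                         overdispersion = 1.2,
                         hemisphere = c("north", "south"),
                         missing_rate = 0,
                         lag_max = 10L, lag_decay = 0.6,
                         locations_per_country = 2L,
                         countries_per_region = 3L,
                         seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(years >= 1, length(heat_log_rr_per_degree) == 4,
            length(dow_effects) == 7, overdispersion >= 1,
            missing_rate >= 0, missing_rate < 1,
            heat_threshold_quantile > 0, heat_threshold_quantile < 1)
  if (abs(temp_ar1) >= 1) stop("temp_ar1 must have absolute value < 1")
  sc <- as.list(environment())
  class(sc) <- "sim_scenario"
  sc
}

# normalized geometric lag weights
true_lag_weights <- function(scenario) {
  w <- scenario$lag_decay^(0:scenario$lag_max)
  w / sum(w)
}

#' Simulate a location's daily temperatures
#'
#' tmean is an annual sinusoid (peaking mid-summer for the scenario's
#' hemisphere) plus AR(1) noise with innovation SD `temp_daily_sd`; tmin
#' and tmax are tmean minus/plus half a positive diurnal range drawn per
#' day. Reproducible given the scenario seed and the location index.
#'
#' @param scenario a `sim_scenario`.
#' @param location_index integer >= 1.
#' @return a `location_series` with deaths all NA (filled by
#'   [simulate_deaths()]).
#' @export
simulate_temperature <- function(scenario, location_index = 1L) {
  set.seed(scenario$seed + 1009L * location_index)
  n <- round(scenario$years * 365.25)
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  peak <- if (scenario$hemisphere == "north") 212 else 31  # late Jul / late Jan
  seasonal <- scenario$temp_seasonal_amplitude *
    cos(2 * pi * (doy - peak) / 365.25)
  innov <- stats::rnorm(n, 0, scenario$temp_daily_sd)
  resid <- as.numeric(stats::filter(innov, scenario$temp_ar1,
                                    method = "recursive"))
  tmean <- scenario$temp_mean_annual + seasonal + resid
  half_range <- abs(stats::rnorm(n, scenario$diurnal_range_mean,
                                 scenario$diurnal_range_sd)) / 2
  rh <- pmin(100, pmax(10, stats::rnorm(n, 70, 12)))  # for humidity runs
  new_location_series(
    location_id = sprintf("loc%02d", location_index),
    dates = dates, deaths = rep(NA_real_, n),
    tmean = tmean, tmin = tmean - half_range, tmax = tmean + half_range,
    rh = rh
  )
}

#' Simulate daily death counts for simulated temperatures
#'
#' The expected count is baseline x seasonal factor x day-of-week factor
#' x exp(cumulative heat effect), where the cumulative heat effect on day
#' t is slope[q(t)] * sum_l w_l * max(0, tmean[t-l] - threshold): q(t) is
#' the day's TV quartile (TV window 1 day, warm-season-relative
#' cutpoints), w the true geometric lag weights, and the threshold the
#' scenario quantile of the location's warm-season tmean. Counts are
#' Poisson when overdispersion is 1, otherwise negative binomial with
#' variance theta * mu. The caller controls the random seed.
#'
#' @param temps a `location_series` with complete temperatures.
#' @param scenario a `sim_scenario`.
#' @return list with `deaths` and `truth` (threshold, slopes, lag
#'   weights, per-day expected counts `mu`, cumulative log-RR
#'   `cum_logrr`, quartile labels, warm-season months, TV cutpoints).
#' @export
simulate_deaths <- function(temps, scenario) {
  n <- length(temps$dates)
  tv <- compute_tv(temps$tmin, temps$tmax, 1L)
  warm_months <- detect_warm_season(temps$dates, temps$tmean, 4L)
  warm <- as.integer(format(temps$dates, "%m")) %in% warm_months
  q <- assign_quartiles(tv, warm)
  qi <- as.integer(q$labels)
  qi[is.na(qi)] <- 2L                      # TV undefined on day 1 only
  thr <- unname(stats::quantile(temps$tmean[warm],
                                scenario$heat_threshold_quantile, type = 7))
  w <- true_lag_weights(scenario)
  exceed <- pmax(0, temps$tmean - thr)
  burden <- numeric(n)
  for (l in 0:scenario$lag_max) {
    idx <- pmax(seq_len(n) - l, 1L)        # pad pre-series lags with day 1
    burden <- burden + w[l + 1L] * exceed[idx]
  }
  cum_logrr <- scenario$heat_log_rr_per_degree[qi] * burden
  doy <- as.integer(format(temps$dates, "%j"))
  peak <- if (scenario$hemisphere == "north") 212 else 31
  winter_peak <- ((peak + 182.625 - 1) %% 365.25) + 1
  seasonal <- 1 + scenario$seasonal_amplitude_deaths *
    cos(2 * pi * (doy - winter_peak) / 365.25)
  dow <- scenario$dow_effects[as.integer(format(temps$dates, "%u"))]
  mu <- scenario$baseline_deaths * seasonal * dow * exp(cum_logrr)
  theta <- scenario$overdispersion
  deaths <- if (theta == 1) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = mu / (theta - 1))
  list(deaths = as.numeric(deaths),
       truth = list(threshold = thr,
                    slopes = scenario$heat_log_rr_per_degree,
                    lag_weights = w, mu = mu, cum_logrr = cum_logrr,
                    quartile = qi, warm_months = warm_months,
                    tv_cutpoints = q$cutpoints))
}

#' Generate a complete synthetic multi-location study
#'
#' Simulates temperatures and deaths for every location, attaches the
#' country/region grouping implied by the scenario, injects missingness
#' completely at random after generation, and returns a per-location
#' truth record sufficient to compute the analytic attributable fraction
#' of the simulated process day by day.
#'
#' @param scenario a `sim_scenario`.
#' @return list with `series` (named list of `location_series`), `truth`
#'   (per-location truth records), and `grouping` (data frame
#'   location_id/country_id/region_id).
#' @export
make_study <- function(scenario) {
  ser <- list(); truth <- list()
  ids <- character(scenario$n_locations)
  for (i in seq_len(scenario$n_locations)) {
    temps <- simulate_temperature(scenario, i)
    set.seed(scenario$seed + 1009L * i + 499L)
    dd <- simulate_deaths(temps, scenario)
    temps$deaths <- dd$deaths
    ctry <- sprintf("country%02d", ceiling(i / scenario$locations_per_country))
    regn <- sprintf("region%02d",
                    ceiling(ceiling(i / scenario$locations_per_country) /
                              scenario$countries_per_region))
    temps$country_id <- ctry; temps$region_id <- regn
    if (scenario$missing_rate > 0) {
      for (fld in c("deaths", "tmean", "tmin", "tmax")) {
        drop <- stats::runif(length(temps[[fld]])) < scenario$missing_rate
        temps[[fld]][drop] <- NA_real_
      }
    }
    ids[i] <- temps$location_id
    ser[[temps$location_id]] <- temps
    truth[[temps$location_id]] <- dd$truth
  }
  grouping <- data.frame(
    location_id = ids,
    country_id = vapply(ser, function(s) s$country_id, character(1)),
    region_id = vapply(ser, function(s) s$region_id, character(1)),
    row.names = NULL
  )
  list(series = ser, truth = truth, grouping = grouping)
}
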