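# shared fixtures, built in code and memoized for the test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

# a small complete 2-location study with a strong Q4-only effect
small_study <- function() {
  memo("small_study", function() {
    sc <- sim_scenario(n_locations = 2, years = 3, baseline_deaths = 25,
                       heat_log_rr_per_degree = c(0, 0, 0, log(1.15) / 5),
                       overdispersion = 1, seed = 101)
    make_study(sc)
  })
}

# one fitted location from the small study, with curves
small_fit <- function() {
  memo("small_fit", function() {
    st <- small_study()
    cfg <- default_config()
    ex <- build_exposure(st$series[[1]], cfg)
    fit <- fit_location_model(st$series[[1]], ex, cfg)
    list(series = st$series[[1]], exposure = ex, fit = fit,
         curves = extract_quartile_curves(fit), truth = st$truth[[1]])
  })
}

# a crossbasis spec on a simple temperature scale
toy_spec <- function(center = 15) {
  crossbasis_spec(var_knots = c(15, 22), var_boundary = c(5, 30),
                  lag_max = 10L, center = center)
}

# quartile_curves object with fully controlled coefficients
fake_curves <- function(coef, vcov, spec = toy_spec(),
                        warm_temps = seq(5, 30, length.out = 501),
                        location_id = "toy", country_id = "toyland") {
  vd <- spec$var_df
  stopifnot(length(coef) == 4 * vd)
  structure(list(coef = coef, vcov = vcov, var_df = vd, spec = spec,
                 warm_temps = warm_temps, location_id = location_id,
                 country_id = country_id, region_id = country_id),
            class = "quartile_curves")
}

# independent natural cubic spline via the truncated power construction:
# basis of all natural cubic splines with the given interior + boundary
# knots (linear beyond the boundary), dimension #interior + 2 incl.
# intercept; used as the alternative parameterization oracle.
tp_natural_spline <- function(x, interior, boundary) {
  kn <- sort(c(boundary[1], interior, boundary[2]))
  K <- length(kn)
  dk <- function(x, k) {
    (pmax(0, x - k)^3 - pmax(0, x - kn[K])^3) / (kn[K] - k)
  }
  cols <- list(1, x)
  for (j in seq_len(K - 2))
    cols[[j + 2]] <- dk(x, kn[j]) - dk(x, kn[K - 1])
  do.call(cbind, cols)
}

# minimal hand-rolled series constructor for toy attribution cases
toy_series <- function(n = 30, deaths, tmean, start = as.Date("2005-07-01")) {
  new_location_series("toy", dates = seq(start, by = "day", length.out = n),
                      deaths = deaths, tmean = tmean,
                      tmin = tmean - 4, tmax = tmean + 4)
}
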