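#' Default run configuration
#'
#' Returns the configuration used by the primary analysis: temperature
#' variability (TV) computed over the current day plus 1 preceding day,
#' a distributed lag window of 0--10 days, temperature spline knots at the
#' 50th and 90th percentiles of the location's warm-season distribution,
#' 2 log-spaced lag knots, a calendar-time natural spline with 4 df per
#' year, the warmest 4 consecutive months as the warm season, and 1,000
#' Monte Carlo draws for attributable-fraction confidence intervals.
#'
#' @param ... named overrides for any configuration field.
#' @return A list of class `tv_config` with fields `tv_window_days`,
#'   `lag_max`, `var_knot_percentiles`, `n_lag_knots`, `time_df_per_year`,
#'   `warm_season_months`, `rh_df`, `mc_draws`, `seed`, `alpha`,
#'   `impute`, `quartile_specific_mmt`, `grouping`.
#' @examples
#' cfg <- default_config()
#' cfg$lag_max
#' default_config(tv_window_days = 3)$tv_window_days
#' @export
default_config <- function(...) {
  cfg <- list(
    tv_window_days = 1L,
    lag_max = 10L,
    var_knot_percentiles = c(50, 90),
    n_lag_knots = 2L,
    time_df_per_year = 4,
    warm_season_months = 4L,
    rh_df = NULL,
    mc_draws = 1000L,
    seed = 1L,
    alpha = 0.05,
    impute = FALSE,
    quartile_specific_mmt = TRUE,
    grouping = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "tv_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `tv_config` list.
#' @return `cfg`, invisibly, after checking invariants.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$tv_window_days >= 1, cfg$lag_max >= 1, cfg$mc_draws >= 1)
  p <- cfg$var_knot_percentiles
  if (any(p <= 0) || any(p >= 100) || any(diff(p) <= 0))
    stop("var_knot_percentiles must be strictly increasing in (0, 100)")
  if (!cfg$warm_season_months %in% 2:4)
    stop("warm_season_months must be 2, 3 or 4")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the fields of [default_config()]; unspecified keys keep
#' their defaults. A `grouping` key may map location ids to
#' `country`/`region` labels.
#'
#' @param path path to a YAML file.
#' @return A `tv_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}
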