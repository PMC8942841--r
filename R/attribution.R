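#' Locate the minimum mortality temperature (MMT)
#'
#' Argmin of the cumulative log-RR over a fine temperature grid (0.1
#' degree C steps) restricted to a percentile range of the warm-season
#' temperature distribution; ties go to the lowest temperature.
#'
#' @param red_coef reduced coefficient vector (length var_df).
#' @param spec the `crossbasis_spec`.
#' @param temps warm-season temperature sample defining percentiles.
#' @param search_percentiles length-2 percentile range (default 1-99;
#'   the extremes are excluded because the curve is unstable there).
#' @return list with `temp` (degrees C), `percentile`, and `range` (the
#'   temperature search bounds used).
#' @export
find_mmt <- function(red_coef, spec, temps, search_percentiles = c(1, 99)) {
  stopifnot(length(search_percentiles) == 2,
            search_percentiles[1] < search_percentiles[2])
  bounds <- stats::quantile(temps, search_percentiles / 100, type = 7)
  if (diff(bounds) <= 0) stop("empty MMT search range")
  grid <- seq(bounds[1], bounds[2], by = 0.1)
  logrr <- drop(var_basis(spec, grid) %*% red_coef)
  mmt <- grid[which.min(logrr)]    # first minimum = lowest temperature on ties
  list(temp = mmt, percentile = 100 * mean(temps <= mmt),
       range = unname(bounds))
}

#' Attributable deaths over a series for one TV quartile
#'
#' Backward attributable-risk perspective: for each warm-season day t in
#' quartile q with tmean above the MMT and inside the target interval,
#' the deaths attributable to heat are deaths_t * (1 - 1/RR_q(tmean_t)),
#' where RR_q is the overall cumulative (lag-summed) relative risk
#' centred at the MMT; the day's deaths are attributed backward to its
#' own exposure history. Days outside the interval or quartile
#' contribute zero.
#'
#' @param series a `location_series`.
#' @param exposure an `exposure_table`.
#' @param curves a `quartile_curves` (typically the BLUP curves).
#' @param mmt MMT for the quartile (from [find_mmt()] or a number).
#' @param quartile 1-4 or "Q1".."Q4".
#' @param range temperature interval (lo, hi]; days qualify when tmean >
#'   max(mmt, lo) and tmean <= hi. Default the whole range above MMT.
#' @param coef optional replacement coefficient vector for the
#'   quartile's block (used by the Monte Carlo draws).
#' @return the attributable number of deaths (AN).
#' @export
attributable_deaths <- function(series, exposure, curves, mmt, quartile,
                                range = c(-Inf, Inf), coef = NULL) {
  q <- if (is.character(quartile)) match(quartile, paste0("Q", 1:4)) else quartile
  mmt_temp <- if (is.list(mmt)) mmt$temp else mmt
  co <- if (is.null(coef)) curves$coef[quartile_block(curves, q)] else coef
  sel <- attribution_days(series, exposure, mmt_temp, q, range)
  if (!any(sel)) return(0)
  rr <- exp(cumulative_logrr(co, curves$spec, series$tmean[sel],
                             center = mmt_temp))
  sum(series$deaths[sel] * (1 - 1 / rr))
}

# days qualifying for attribution: warm season, quartile q, tmean above
# max(mmt, lo) and at most hi, with observed deaths and temperature
attribution_days <- function(series, exposure, mmt_temp, q, range) {
  exposure$warm_season & !is.na(series$deaths) & !is.na(series$tmean) &
    !is.na(exposure$tv_quartile) & as.integer(exposure$tv_quartile) == q &
    series$tmean > max(mmt_temp, range[1]) & series$tmean <= range[2]
}

#' Attributable fractions from component attributable numbers
#'
#' AF = 100 * AN / total deaths, per component and overall.
#'
#' @param an_by_component named numeric vector of attributable numbers.
#' @param total_deaths total death count (> 0).
#' @return named numeric vector of percentages, with an added `total`
#'   element (the sum of the components).
#' @export
af_components <- function(an_by_component, total_deaths) {
  if (total_deaths <= 0) stop("total_deaths must be positive")
  af <- 100 * an_by_component / total_deaths
  c(af, total = sum(af))
}

#' Full attribution for one location with Monte Carlo empirical CIs
#'
#' Computes, per TV quartile, the heat-attributable deaths above the
#' quartile's MMT, decomposed into the components (MMT, TVST] and
#' (TVST, Inf), and attaches 95% empirical CIs from Monte Carlo draws of
#' the stacked curve coefficients (multivariate normal at the supplied
#' mean and covariance; MMT and TVST are held fixed across draws).
#'
#' @param series a `location_series`.
#' @param exposure an `exposure_table`.
#' @param curves a `quartile_curves` (typically BLUPs).
#' @param tvst_temp the location's TVST in degrees C (its country's TVST
#'   percentile mapped through the location's warm-season temperature
#'   distribution); NA disables the decomposition (components equal the
#'   total and zero).
#' @param mmt list of 4 MMT entries (one per quartile) or a single entry
#'   reused for all quartiles.
#' @param n_draws Monte Carlo draws.
#' @param seed RNG seed for the draws.
#' @param level CI level.
#' @return list of class `attribution_result`: `table` (data frame with
#'   quartile, component, an and its CI bounds, `af` with CI bounds
#'   [denominator: all warm-season deaths], `component_deaths`, and
#'   `af_in_component` [denominator: deaths on the component's own
#'   qualifying days]), `total_deaths`, `draws` (matrix n_draws x 8 of
#'   component ANs), `n_draws`, `seed`.
#' @export
attribute_location <- function(series, exposure, curves, tvst_temp, mmt,
                               n_draws = 1000L, seed = 1L, level = 0.95) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.list(mmt[[1]])) mmt <- rep(list(mmt), 4L)
  tv_hi <- if (is.na(tvst_temp)) Inf else tvst_temp
  total_deaths <- sum(series$deaths[exposure$warm_season &
                                      !is.na(series$deaths)])
  components <- list(between = c(-Inf, tv_hi), above = c(tv_hi, Inf))

  an_for <- function(q, coef_q) {
    vapply(components, function(rg)
      attributable_deaths(series, exposure, curves, mmt[[q]], q,
                          range = rg, coef = coef_q), numeric(1))
  }
  point <- do.call(rbind, lapply(1:4, function(q) an_for(q, NULL)))
  comp_deaths <- do.call(rbind, lapply(1:4, function(q)
    vapply(components, function(rg)
      sum(series$deaths[attribution_days(series, exposure, mmt[[q]]$temp,
                                         q, rg)]), numeric(1))))

  set.seed(seed)
  zero_vc <- max(abs(curves$vcov)) == 0
  draws <- matrix(NA_real_, n_draws, 8L)
  coefs <- if (zero_vc)
    matrix(curves$coef, n_draws, length(curves$coef), byrow = TRUE)
  else MASS::mvrnorm(n_draws, curves$coef, (curves$vcov + t(curves$vcov)) / 2)
  for (d in seq_len(n_draws)) {
    row <- unlist(lapply(1:4, function(q)
      an_for(q, coefs[d, quartile_block(curves, q)])))
    draws[d, ] <- row
  }
  colnames(draws) <- paste0("Q", rep(1:4, each = 2), "_",
                            rep(c("between", "above"), 4))

  alpha2 <- (1 - level) / 2
  tab <- do.call(rbind, lapply(1:4, function(q) {
    comps <- c("between", "above", "total")
    an <- c(point[q, ], sum(point[q, ]))
    dr <- cbind(draws[, (q - 1) * 2 + 1], draws[, (q - 1) * 2 + 2])
    dr <- cbind(dr, rowSums(dr))
    data.frame(quartile = paste0("Q", q), component = comps,
               an = an,
               an_lo = apply(dr, 2, stats::quantile, alpha2, type = 7),
               an_hi = apply(dr, 2, stats::quantile, 1 - alpha2, type = 7),
               component_deaths = c(comp_deaths[q, ], sum(comp_deaths[q, ])),
               row.names = NULL)
  }))
  tab$af <- 100 * tab$an / total_deaths
  tab$af_lo <- 100 * tab$an_lo / total_deaths
  tab$af_hi <- 100 * tab$an_hi / total_deaths
  tab$af_in_component <- ifelse(tab$component_deaths > 0,
                                100 * tab$an / tab$component_deaths, NA)
  structure(list(table = tab, total_deaths = total_deaths, draws = draws,
                 n_draws = n_draws, seed = seed, level = level,
                 location_id = series$location_id,
                 country_id = series$country_id,
                 region_id = series$region_id),
            class = "attribution_result")
}

#' Aggregate attribution results across locations
#'
#' Attributable numbers are summed across member locations draw by draw
#' (Monte Carlo draws aligned by index), so the aggregated empirical CIs
#' come from the distribution of the summed draws; AF = 100 * sum(AN) /
#' sum(total deaths).
#'
#' @param results list of `attribution_result` for the member locations.
#' @param scope label for the aggregate (e.g. a country id or "global").
#' @return an `attribution_result` for the group (without per-draw
#'   seeds).
#' @export
aggregate_attribution <- function(results, scope = "global") {
  stopifnot(length(results) >= 1)
  nd <- vapply(results, function(r) r$n_draws, numeric(1))
  if (length(unique(nd)) != 1) stop("Monte Carlo draw counts differ")
  level <- results[[1]]$level
  draws <- Reduce(`+`, lapply(results, function(r) r$draws))
  point <- Reduce(`+`, lapply(results, function(r)
    matrix(r$table$an[r$table$component != "total"], 4, 2, byrow = TRUE)))
  comp_deaths <- Reduce(`+`, lapply(results, function(r)
    matrix(r$table$component_deaths[r$table$component != "total"], 4, 2,
           byrow = TRUE)))
  total_deaths <- sum(vapply(results, function(r) r$total_deaths, numeric(1)))
  alpha2 <- (1 - level) / 2
  tab <- do.call(rbind, lapply(1:4, function(q) {
    an <- c(point[q, ], sum(point[q, ]))
    dr <- cbind(draws[, (q - 1) * 2 + 1], draws[, (q - 1) * 2 + 2])
    dr <- cbind(dr, rowSums(dr))
    data.frame(quartile = paste0("Q", q),
               component = c("between", "above", "total"),
               an = an,
               an_lo = apply(dr, 2, stats::quantile, alpha2, type = 7),
               an_hi = apply(dr, 2, stats::quantile, 1 - alpha2, type = 7),
               component_deaths = c(comp_deaths[q, ], sum(comp_deaths[q, ])),
               row.names = NULL)
  }))
  tab$af <- 100 * tab$an / total_deaths
  tab$af_lo <- 100 * tab$an_lo / total_deaths
  tab$af_hi <- 100 * tab$an_hi / total_deaths
  tab$af_in_component <- ifelse(tab$component_deaths > 0,
                                100 * tab$an / tab$component_deaths, NA)
  structure(list(table = tab, total_deaths = total_deaths, draws = draws,
                 n_draws = nd[1], seed = NA_integer_, level = level,
                 location_id = scope, country_id = scope, region_id = scope),
            class = "attribution_result")
}
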