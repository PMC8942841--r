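#' Temperature variability (TV)
#'
#' TV on day t is the sample standard deviation of the pooled daily
#' minimum and maximum temperatures over the current day and the
#' preceding `window_days` days: the 2*(window_days+1) values
#' \{tmin[t-l], tmax[t-l] : l = 0..window_days\}. The default window of 1
#' day uses the four values Tmin-lag0, Tmax-lag0, Tmin-lag1, Tmax-lag1.
#' TV is missing whenever any constituent temperature is missing; the
#' first `window_days` days are missing by construction.
#'
#' TV is translation-invariant and scales linearly with the temperatures.
#'
#' @param tmin,tmax aligned daily series, degrees C.
#' @param window_days number of preceding days included (>= 1).
#' @return numeric vector of TV values, degrees C.
#' @examples
#' compute_tv(c(10, 10), c(20, 20), 1)  # day 2: sd(c(10,20,10,20)) = 5.7735
#' @export
compute_tv <- function(tmin, tmax, window_days = 1L) {
  if (window_days < 1) stop("window_days must be >= 1")
  n <- length(tmin)
  stopifnot(length(tmax) == n)
  w <- as.integer(window_days)
  if (n <= w) return(rep(NA_real_, n))
  # columns: tmin and tmax at lags 0..w
  mats <- vector("list", 2L * (w + 1L))
  for (l in 0:w) {
    shift <- function(x) c(rep(NA_real_, l), x[seq_len(n - l)])
    mats[[2L * l + 1L]] <- shift(tmin)
    mats[[2L * l + 2L]] <- shift(tmax)
  }
  m <- do.call(cbind, mats)
  tv <- apply(m, 1L, stats::sd)    # sample SD, divisor 2(w+1)-1; NA if any NA
  tv[rowSums(is.na(m)) > 0] <- NA_real_
  tv
}

#' Assign location-relative TV quartiles
#'
#' Cutpoints are the 25th/50th/75th empirical percentiles (linear
#' interpolation between order statistics) of the warm-season TV values
#' within the location, so stratification is relative to the location's
#' own TV distribution. Intervals are right-closed: Q1 if tv <= c1, Q2 if
#' c1 < tv <= c2, Q3 if c2 < tv <= c3, else Q4. All days with a defined
#' TV are labelled using the warm-season cutpoints.
#'
#' @param tv TV series from [compute_tv()].
#' @param warm_mask logical mask of warm-season days.
#' @return list with `labels` (factor Q1..Q4, NA where tv missing) and
#'   `cutpoints` (3 values).
#' @export
assign_quartiles <- function(tv, warm_mask) {
  vals <- tv[warm_mask & !is.na(tv)]
  if (length(vals) < 8) stop("need at least 8 defined warm-season TV values")
  if (diff(range(vals)) == 0) {
    warning("all TV values identical; all days labelled Q1", call. = FALSE)
    cut <- rep(vals[1], 3)
    lab <- factor(ifelse(is.na(tv), NA, "Q1"), levels = paste0("Q", 1:4))
    return(list(labels = lab, cutpoints = cut))
  }
  cut <- unname(stats::quantile(vals, c(0.25, 0.50, 0.75), type = 7))
  q <- rep(NA_integer_, length(tv))
  ok <- !is.na(tv)
  q[ok] <- 1L + (tv[ok] > cut[1]) + (tv[ok] > cut[2]) + (tv[ok] > cut[3])
  list(labels = factor(paste0("Q", q), levels = paste0("Q", 1:4)),
       cutpoints = cut)
}

#' Detect the warm season
#'
#' The warm season is the set of `n_months` consecutive calendar months
#' (possibly wrapping December to January) maximizing the mean of tmean
#' over all observed days falling in those months. Ties are broken by the
#' earliest starting month in calendar order.
#'
#' @param dates Date vector spanning at least one full year.
#' @param tmean daily mean temperatures.
#' @param n_months window length, 2 to 4.
#' @return integer vector of the selected calendar months (1-12), in
#'   window order starting at the window's first month.
#' @export
detect_warm_season <- function(dates, tmean, n_months = 4L) {
  stopifnot(n_months %in% 2:4)
  if (as.numeric(max(dates) - min(dates)) < 364)
    stop("need at least one full year of data")
  mon <- as.integer(format(dates, "%m"))
  ok <- !is.na(tmean)
  counts <- tabulate(mon[ok], 12L)
  if (any(counts == 0)) stop("calendar month with zero observations: ",
                             paste(which(counts == 0), collapse = ", "))
  sums <- vapply(1:12, function(m) sum(tmean[ok & mon == m]), numeric(1))
  best <- -Inf; best_start <- 1L
  for (s in 1:12) {
    months <- ((s - 1L + 0:(n_months - 1L)) %% 12L) + 1L
    avg <- sum(sums[months]) / sum(counts[months])
    if (avg > best + 1e-12) { best <- avg; best_start <- s }
  }
  ((best_start - 1L + 0:(n_months - 1L)) %% 12L) + 1L
}

#' Build the exposure table for one location
#'
#' Computes TV over the configured window, detects the warm season, and
#' assigns location-relative TV quartiles.
#'
#' @param series a `location_series`.
#' @param config a `tv_config`.
#' @return list of class `exposure_table` with fields `tv`,
#'   `tv_quartile` (factor), `warm_season` (logical), `cutpoints`,
#'   `warm_months`.
#' @export
build_exposure <- function(series, config = default_config()) {
  tv <- compute_tv(series$tmin, series$tmax, config$tv_window_days)
  warm_months <- detect_warm_season(series$dates, series$tmean,
                                    config$warm_season_months)
  warm <- as.integer(format(series$dates, "%m")) %in% warm_months
  q <- assign_quartiles(tv, warm)
  structure(list(tv = tv, tv_quartile = q$labels, warm_season = warm,
                 cutpoints = q$cutpoints, warm_months = warm_months),
            class = "exposure_table")
}
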