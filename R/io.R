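#' Read daily location series from a delimited file
#'
#' Expects a CSV with header columns `location_id`, `date` (ISO-8601),
#' `deaths`, `tmean`, `tmin`, `tmax` and optionally `rh` (relative
#' humidity, percent). Empty strings and "NA" are treated as missing.
#' Rows are split by `location_id` and sorted by date. Rows violating the
#' temperature ordering tmin <= tmean <= tmax are reported in a validation
#' attribute (a warning, not an error).
#'
#' @param path path to the CSV file.
#' @param grouping optional data frame with columns `location_id`,
#'   `country_id`, `region_id`; locations absent from it fall back to
#'   their own id for both levels.
#' @return A named list of `location_series` objects (one per location),
#'   each a list with fields `location_id`, `country_id`, `region_id`,
#'   `dates` (Date), `deaths`, `tmean`, `tmin`, `tmax`, `rh` (or NULL),
#'   and a `validation` data frame of flagged rows.
#' @export
read_location_series <- function(path, grouping = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("", "NA"), check.names = FALSE)
  mandatory <- c("location_id", "date", "deaths", "tmean", "tmin", "tmax")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(df$date))
  if (length(bad))
    stop("unparseable date at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (anyNA(dates)) stop("missing date at row(s): ",
                         paste(utils::head(which(is.na(dates)), 5), collapse = ", "))
  df$date <- dates
  num <- function(x) suppressWarnings(as.numeric(x))
  df$deaths <- num(df$deaths); df$tmean <- num(df$tmean)
  df$tmin <- num(df$tmin); df$tmax <- num(df$tmax)
  has_rh <- "rh" %in% names(df)
  if (has_rh) df$rh <- num(df$rh)

  out <- lapply(split(df, df$location_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    if (anyDuplicated(d$date)) stop("duplicate dates for location ", d$location_id[1])
    loc <- d$location_id[1]
    grp <- lookup_grouping(loc, grouping)
    s <- new_location_series(
      location_id = loc, country_id = grp$country_id, region_id = grp$region_id,
      dates = d$date, deaths = d$deaths,
      tmean = d$tmean, tmin = d$tmin, tmax = d$tmax,
      rh = if (has_rh) d$rh else NULL
    )
    s
  })
  out[order(names(out))]
}

lookup_grouping <- function(loc, grouping) {
  if (is.null(grouping)) return(list(country_id = loc, region_id = loc))
  i <- match(loc, grouping$location_id)
  if (is.na(i)) return(list(country_id = loc, region_id = loc))
  list(country_id = grouping$country_id[i], region_id = grouping$region_id[i])
}

#' Construct a location series
#'
#' Validates the daily-series invariants: strictly increasing dates,
#' nonnegative integer death counts where present, and (as a warning
#' recorded in the `validation` field) tmin <= tmean <= tmax.
#'
#' @param location_id,country_id,region_id identifiers.
#' @param dates Date vector, strictly increasing.
#' @param deaths nonnegative integer counts (NA allowed).
#' @param tmean,tmin,tmax daily temperatures, degrees C (NA allowed).
#' @param rh optional relative humidity, percent.
#' @return A `location_series` list.
#' @export
new_location_series <- function(location_id, country_id = location_id,
                                region_id = location_id,
                                dates, deaths, tmean, tmin, tmax, rh = NULL) {
  n <- length(dates)
  stopifnot(length(deaths) == n, length(tmean) == n,
            length(tmin) == n, length(tmax) == n)
  if (n > 1 && any(diff(as.numeric(dates)) <= 0))
    stop("dates must be strictly increasing for location ", location_id)
  obs <- !is.na(deaths)
  if (any(deaths[obs] < 0) || any(deaths[obs] != round(deaths[obs])))
    stop("deaths must be nonnegative integers for location ", location_id)
  complete_t <- !is.na(tmin) & !is.na(tmean) & !is.na(tmax)
  viol <- which(complete_t & (tmin > tmean | tmean > tmax))
  validation <- data.frame(row = viol,
                           issue = rep("temperature ordering tmin<=tmean<=tmax violated",
                                       length(viol)))
  if (length(viol))
    warning(sprintf("location %s: %d row(s) violate temperature ordering",
                    location_id, length(viol)), call. = FALSE)
  structure(list(location_id = location_id, country_id = country_id,
                 region_id = region_id, dates = dates, deaths = deaths,
                 tmean = tmean, tmin = tmin, tmax = tmax, rh = rh,
                 validation = validation),
            class = "location_series")
}

#' Write location series to a CSV file
#'
#' Inverse of [read_location_series()]; round-trips values at full
#' precision (15 significant digits).
#'
#' @param series list of `location_series`.
#' @param path output path.
#' @export
write_location_series <- function(series, path) {
  rows <- lapply(series, function(s) {
    d <- data.frame(location_id = s$location_id,
                    date = format(s$dates, "%Y-%m-%d"),
                    deaths = s$deaths, tmean = s$tmean,
                    tmin = s$tmin, tmax = s$tmax)
    if (!is.null(s$rh)) d$rh <- s$rh
    d
  })
  df <- do.call(rbind, rows)
  num_cols <- setdiff(names(df), c("location_id", "date"))
  for (cl in num_cols) {
    v <- sprintf("%.15g", df[[cl]])
    v[is.na(df[[cl]])] <- NA
    df[[cl]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Fill interior gaps of a numeric series by natural cubic spline
#' interpolation
#'
#' Used in sensitivity analyses; observed values are never altered.
#' Extrapolation is refused: the first and last entries must be present.
#'
#' @param values numeric vector with NA gaps.
#' @return the vector with gaps filled.
#' @examples
#' impute_series(c(1, 2, NA, 4, 5))  # gap filled with 3
#' @export
impute_series <- function(values) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  if (miss[1] || miss[length(values)])
    stop("leading or trailing missing values: extrapolation refused")
  idx <- seq_along(values)
  f <- stats::splinefun(idx[!miss], values[!miss], method = "natural")
  values[miss] <- f(idx[miss])
  values
}
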