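#' Fit the location-specific quasi-Poisson model
#'
#' Fits, on warm-season days with complete outcome and covariates, the
#' log-link quasi-Poisson regression
#'
#'   E(Y_t) = exp(alpha + beta TV_t + cb(tmean, lag) +
#'                cb(tmean, lag) x Q2/Q3/Q4 dummies +
#'                ns(time, 4 df/year) + dow + [ns(rh, rh_df)])
#'
#' where cb is the tensor-product cross-basis of a natural cubic spline
#' of temperature (interior knots at the configured warm-season
#' percentiles, boundary at the warm-season range) and a natural cubic
#' spline of lag with log-spaced knots. The interaction uses the TV
#' quartile of the cross-basis row's own day. Point estimates equal the
#' Poisson ML estimates; the dispersion is the Pearson chi-square over
#' residual df and scales the covariance.
#'
#' @param series a `location_series`.
#' @param exposure an `exposure_table` from [build_exposure()].
#' @param config a `tv_config`.
#' @return list of class `stage1_fit`: `coef`, `vcov`, `dispersion`,
#'   `converged`, `n_days_used`, `spec` (the `crossbasis_spec`),
#'   `idx` (column indices of the cross-basis main and interaction
#'   blocks), `warm_temps` (warm-season tmean sample for percentile
#'   maps), `location_id`, `country_id`, `region_id`.
#' @export
fit_location_model <- function(series, exposure, config = default_config()) {
  warm <- exposure$warm_season
  wt <- series$tmean[warm & !is.na(series$tmean)]
  var_knots <- unname(stats::quantile(wt, config$var_knot_percentiles / 100,
                                      type = 7))
  spec <- crossbasis_spec(var_knots = var_knots, var_boundary = range(wt),
                          lag_max = config$lag_max,
                          lag_knots = log_lag_knots(config$lag_max,
                                                    config$n_lag_knots),
                          center = stats::median(wt))
  cb <- build_crossbasis(series$tmean, spec)
  ncb <- ncol(cb)

  use <- warm & !is.na(series$deaths) & !is.na(exposure$tv) &
    !is.na(exposure$tv_quartile) & rowSums(is.na(cb)) == 0
  if (!is.null(config$rh_df)) use <- use & !is.na(series$rh)
  if (sum(use) < 1) stop("no usable rows for location ", series$location_id)
  span_years <- as.numeric(diff(range(series$dates[use])) + 1) / 365.25
  if (span_years < 1.9)
    stop("location ", series$location_id,
         " has fewer than 2 consecutive years of usable warm-season data")

  qi <- as.integer(exposure$tv_quartile[use])
  cbu <- cb[use, , drop = FALSE]
  time_df <- max(1L, round(config$time_df_per_year * span_years))
  time_basis <- splines::ns(as.numeric(series$dates[use]), df = time_df)
  dow <- factor(format(series$dates[use], "%u"), levels = as.character(1:7))
  dow_mm <- stats::model.matrix(~dow)[, -1, drop = FALSE]

  X <- cbind(`(Intercept)` = 1, tv = exposure$tv[use], cbu,
             cbu * (qi == 2L), cbu * (qi == 3L), cbu * (qi == 4L),
             time_basis, dow_mm)
  colnames(X) <- c("(Intercept)", "tv", paste0("cb", seq_len(ncb)),
                   paste0("cb", seq_len(ncb), ":Q2"),
                   paste0("cb", seq_len(ncb), ":Q3"),
                   paste0("cb", seq_len(ncb), ":Q4"),
                   paste0("time", seq_len(time_df)),
                   paste0("dow", 2:7))
  if (!is.null(config$rh_df)) {
    rh_b <- splines::ns(series$rh[use], df = config$rh_df)
    colnames(rh_b) <- paste0("rh", seq_len(config$rh_df))
    X <- cbind(X, rh_b)
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design for location ", series$location_id,
         "; collinear column(s): ", paste(dropped, collapse = ", "))
  }

  y <- series$deaths[use]
  fit <- stats::glm.fit(X, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 50))
  mu <- fit$fitted.values
  p <- ncol(X)
  dispersion <- sum((y - mu)^2 / mu) / (length(y) - p)
  XtWX <- crossprod(X * sqrt(fit$weights))
  vc <- dispersion * solve(XtWX)
  dimnames(vc) <- list(colnames(X), colnames(X))

  idx <- list(main = 2L + seq_len(ncb),
              q2 = 2L + ncb + seq_len(ncb),
              q3 = 2L + 2L * ncb + seq_len(ncb),
              q4 = 2L + 3L * ncb + seq_len(ncb))
  structure(list(coef = stats::setNames(fit$coefficients, colnames(X)),
                 vcov = vc, dispersion = dispersion,
                 converged = fit$converged, n_days_used = length(y),
                 spec = spec, idx = idx, warm_temps = sort(wt),
                 location_id = series$location_id,
                 country_id = series$country_id,
                 region_id = series$region_id),
            class = "stage1_fit")
}

#' Extract per-quartile reduced cumulative curves
#'
#' Reduces the cross-basis coefficients to the overall cumulative
#' (lag-summed) association on the temperature basis, per TV quartile:
#' Q1 from the main cross-basis block, Q2-Q4 from main plus the
#' corresponding interaction contrast. The stacked covariance (including
#' cross-quartile blocks, which are needed by the repeated-measures and
#' pointwise tests downstream) is propagated from the full fit
#' covariance through the same linear map.
#'
#' @param fit a `stage1_fit`.
#' @return list of class `quartile_curves`: `coef` (stacked, length
#'   4 * var_df, order Q1..Q4), `vcov` (stacked), `var_df`, `spec`,
#'   `warm_temps`, `location_id`, `country_id`, `region_id`.
#' @export
extract_quartile_curves <- function(fit) {
  spec <- fit$spec
  M <- reduction_map(spec)
  vd <- spec$var_df
  p <- length(fit$coef)
  A <- matrix(0, 4L * vd, p)
  A[1:vd, fit$idx$main] <- M
  for (q in 2:4) {
    rows <- (q - 1L) * vd + seq_len(vd)
    A[rows, fit$idx$main] <- M
    A[rows, fit$idx[[paste0("q", q)]]] <- M
  }
  structure(list(coef = drop(A %*% fit$coef),
                 vcov = A %*% fit$vcov %*% t(A),
                 var_df = vd, spec = spec, warm_temps = fit$warm_temps,
                 location_id = fit$location_id,
                 country_id = fit$country_id, region_id = fit$region_id),
            class = "quartile_curves")
}

# index of quartile q's block in a stacked coefficient vector
quartile_block <- function(curves, q) (q - 1L) * curves$var_df + seq_len(curves$var_df)

#' Cumulative RR curve with pointwise confidence interval
#'
#' RR(x) = exp(sum_j coef_j (B_j(x) - B_j(center))) for the requested
#' quartile, with delta-method pointwise CIs from the reduced covariance.
#' Temperatures outside the basis boundary are flagged with a warning
#' (the natural spline extrapolates linearly).
#'
#' @param curves a `quartile_curves`.
#' @param quartile 1-4 or "Q1".."Q4".
#' @param temps temperatures at which to evaluate.
#' @param center reference temperature; must lie inside the basis
#'   boundary.
#' @param level confidence level.
#' @return data frame with columns `temp`, `logrr`, `se`, `rr`, `lo`,
#'   `hi`.
#' @export
predict_cumulative_rr <- function(curves, quartile, temps,
                                  center = curves$spec$center,
                                  level = 0.95) {
  q <- if (is.character(quartile)) match(quartile, paste0("Q", 1:4)) else quartile
  stopifnot(q %in% 1:4)
  spec <- curves$spec
  if (center < spec$var_boundary[1] || center > spec$var_boundary[2])
    stop("center lies outside the basis boundary")
  if (any(temps < spec$var_boundary[1] | temps > spec$var_boundary[2]))
    warning("some temperatures lie outside the basis boundary (extrapolation)",
            call. = FALSE)
  blk <- quartile_block(curves, q)
  co <- curves$coef[blk]
  Sg <- curves$vcov[blk, blk, drop = FALSE]
  D <- var_basis(spec, temps) -
    matrix(var_basis(spec, center), length(temps), spec$var_df, byrow = TRUE)
  logrr <- drop(D %*% co)
  se <- sqrt(pmax(0, rowSums((D %*% Sg) * D)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(temp = temps, logrr = logrr, se = se,
             rr = exp(logrr), lo = exp(logrr - z * se),
             hi = exp(logrr + z * se))
}
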