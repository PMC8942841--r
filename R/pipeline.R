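#' Run the full two-stage analysis
#'
#' Orchestrates exposure construction, location-specific quasi-Poisson
#' DLNM fits with the TV-quartile interaction, multivariate
#' random-effects pooling with BLUPs at the global, regional and country
#' levels, the repeated-measures quartile-difference test, country-level
#' TVST detection, and decomposed attributable-fraction estimation with
#' Monte Carlo empirical CIs. Locations failing the stage-1
#' preconditions are dropped with a logged reason and pooling proceeds.
#' All sensitivity variants (TV window, warm-season length, lag window,
#' humidity adjustment, imputation) are selected purely through the
#' configuration.
#'
#' @param config a `tv_config`.
#' @param input a `sim_scenario` (synthetic study), a path to a series
#'   CSV, or a named list of `location_series`.
#' @return list of class `tv_run`: `fits`, `curves` (per location),
#'   `blup_curves`, `meta` (global/region/country `meta_fit`s),
#'   `quartile_test`, `mmt` (per quartile, from the global pooled
#'   curves), `tvst` (per-country table), `attribution` (location,
#'   country, region, global), `pooled_curves` (RR grid table),
#'   `dropped`, `truth` (for synthetic input), `manifest`.
#' @export
run_pipeline <- function(config = default_config(), input) {
  t0 <- Sys.time()
  truth <- NULL
  if (inherits(input, "sim_scenario")) {
    study <- make_study(input)
    series <- study$series
    truth <- study$truth
    if (is.null(config$grouping)) config$grouping <- study$grouping
    for (id in names(series)) {
      grp <- lookup_grouping(id, config$grouping)
      series[[id]]$country_id <- grp$country_id
      series[[id]]$region_id <- grp$region_id
    }
  } else if (is.character(input)) {
    series <- read_location_series(input, config$grouping)
  } else {
    series <- input
  }

  warnings_log <- character()
  if (isTRUE(config$impute)) {
    for (id in names(series)) {
      for (fld in c("tmean", "tmin", "tmax")) {
        series[[id]][[fld]] <- tryCatch(impute_series(series[[id]][[fld]]),
                                        error = function(e) series[[id]][[fld]])
      }
    }
  }

  exposures <- lapply(series, build_exposure, config = config)
  fits <- list(); curves <- list(); dropped <- list()
  for (id in names(series)) {
    res <- tryCatch(fit_location_model(series[[id]], exposures[[id]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[id]] <- conditionMessage(res)
      next
    }
    if (!res$converged) {
      dropped[[id]] <- "stage-1 fit did not converge"
      warnings_log <- c(warnings_log,
                        paste0("location ", id, " dropped: non-convergence"))
      next
    }
    fits[[id]] <- res
    curves[[id]] <- extract_quartile_curves(res)
  }
  if (!length(fits)) stop("pipeline stage stage1: no location could be fitted")

  ids <- names(fits)
  ctry <- vapply(fits, function(f) f$country_id, character(1))
  regn <- vapply(fits, function(f) f$region_id, character(1))

  meta_of <- function(sel) {
    mvmeta_re(t(vapply(curves[sel], function(cs) cs$coef,
                       numeric(4 * curves[[1]]$var_df))),
              lapply(curves[sel], function(cs) cs$vcov))
  }
  meta <- list(global = meta_of(ids))
  meta$country <- lapply(split(ids, ctry), meta_of)
  meta$region <- lapply(split(ids, regn), meta_of)

  blups <- compute_blups(meta$global)
  blup_curves <- curves
  for (i in seq_along(ids)) {
    blup_curves[[ids[i]]]$coef <- blups[[i]]$coef
    blup_curves[[ids[i]]]$vcov <- blups[[i]]$vcov
  }

  qtest <- test_quartile_difference(curves)

  # pooled temperature distribution and per-quartile MMT from the global fit
  pooled_temps <- sort(unlist(lapply(curves[ids], function(cs) cs$warm_temps)))
  spec0 <- curves[[1]]$spec
  vd <- curves[[1]]$var_df
  mmt <- lapply(1:4, function(q) {
    co <- meta$global$beta[(q - 1L) * vd + seq_len(vd)]
    find_mmt(co, spec0, pooled_temps)
  })
  names(mmt) <- paste0("Q", 1:4)
  if (!isTRUE(config$quartile_specific_mmt)) {
    common <- find_mmt(Reduce(`+`, lapply(1:4, function(q)
      meta$global$beta[(q - 1L) * vd + seq_len(vd)])) / 4, spec0, pooled_temps)
    mmt <- rep(list(common), 4L); names(mmt) <- paste0("Q", 1:4)
  }

  mmt_pct <- min(vapply(mmt, function(m) m$percentile, numeric(1)))
  grid <- seq(max(1L, ceiling(mmt_pct)), 100L)
  tvst_by_country <- lapply(split(ids, ctry), function(sel)
    find_tvst(curves[sel], grid = grid, alpha = config$alpha,
              center_percentile = 50))
  tvst <- tvst_table(tvst_by_country)

  attribution_loc <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    tvst_pct <- tvst$tvst_percentile[match(ctry[i], tvst$country_id)]
    tvst_temp <- if (is.na(tvst_pct)) NA_real_ else
      unname(stats::quantile(curves[[id]]$warm_temps, tvst_pct / 100, type = 7))
    # the pooled MMT percentile, mapped through the location's own
    # warm-season temperature distribution (MMT is defined on the pooled
    # curves; per-location argmins are unstable at single-location noise)
    mmt_loc <- lapply(1:4, function(q) {
      pct <- mmt[[q]]$percentile
      list(temp = unname(stats::quantile(curves[[id]]$warm_temps,
                                         pct / 100, type = 7)),
           percentile = pct)
    })
    attribution_loc[[id]] <- attribute_location(
      series[[id]], exposures[[id]], blup_curves[[id]], tvst_temp,
      mmt_loc, n_draws = config$mc_draws,
      seed = config$seed + 131L * i + 7L)
  }
  attribution <- list(
    location = attribution_loc,
    country = lapply(split(ids, ctry), function(sel)
      aggregate_attribution(attribution_loc[sel], scope = ctry[match(sel[1], ids)])),
    region = lapply(split(ids, regn), function(sel)
      aggregate_attribution(attribution_loc[sel], scope = regn[match(sel[1], ids)])),
    global = aggregate_attribution(attribution_loc, scope = "global")
  )

  pooled_curves <- pooled_curve_table(meta$global, spec0, pooled_temps, mmt)

  manifest <- list(
    config = config[setdiff(names(config), "grouping")],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tvheat")),
    n_locations_in = length(series), n_locations_fit = length(ids),
    started = format(t0), finished = format(Sys.time()),
    warnings = warnings_log,
    digests = list(
      exposure = digest_obj(lapply(exposures, function(e)
        list(e$tv, as.integer(e$tv_quartile), e$warm_season))),
      stage1 = digest_obj(lapply(fits, function(f) unname(f$coef))),
      meta = digest_obj(meta$global$beta),
      tvst = digest_obj(tvst$tvst_percentile),
      attribution = digest_obj(attribution$global$table[c("an", "an_lo",
                                                          "an_hi")])
    )
  )

  structure(list(fits = fits, curves = curves, blup_curves = blup_curves,
                 meta = meta, quartile_test = qtest, mmt = mmt, tvst = tvst,
                 attribution = attribution, pooled_curves = pooled_curves,
                 dropped = dropped, truth = truth, manifest = manifest),
            class = "tv_run")
}

# RR grid over integer percentiles for the pooled global curves
pooled_curve_table <- function(meta_global, spec, pooled_temps, mmt) {
  vd <- length(meta_global$beta) / 4L
  pct <- 1:99
  xs <- stats::quantile(pooled_temps, pct / 100, type = 7)
  do.call(rbind, lapply(1:4, function(q) {
    blk <- (q - 1L) * vd + seq_len(vd)
    co <- meta_global$beta[blk]
    vc <- meta_global$vcov[blk, blk, drop = FALSE]
    ctr <- mmt[[q]]$temp
    D <- var_basis(spec, xs) -
      matrix(var_basis(spec, ctr), length(xs), vd, byrow = TRUE)
    logrr <- drop(D %*% co)
    se <- sqrt(pmax(0, rowSums((D %*% vc) * D)))
    data.frame(level = "global", quartile = paste0("Q", q),
               percentile = pct, temp = unname(xs), rr = exp(logrr),
               lo = exp(logrr - 1.959964 * se),
               hi = exp(logrr + 1.959964 * se), row.names = NULL)
  }))
}

# md5 digest of any R object via its serialization
digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Write the main result tables of a run to CSV
#'
#' Writes `curves.csv` (level, quartile, percentile, temp, rr, lo, hi),
#' `tvst.csv` (country_id, identified, tvst_percentile, own_percentile)
#' and `attribution.csv` (scope, group, quartile, component, an, an_lo,
#' an_hi, af, af_lo, af_hi) into a directory.
#'
#' @param run a `tv_run`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_run_tables <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$pooled_curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(run$tvst, file.path(dir, "tvst.csv"), row.names = FALSE)
  rows <- list()
  for (scope in c("country", "region")) {
    for (nm in names(run$attribution[[scope]])) {
      t <- run$attribution[[scope]][[nm]]$table
      t$scope <- scope; t$group <- nm
      rows[[paste(scope, nm)]] <- t
    }
  }
  tg <- run$attribution$global$table
  tg$scope <- "global"; tg$group <- "global"
  rows$global <- tg
  af <- do.call(rbind, rows)
  af <- af[, c("scope", "group", "quartile", "component",
               "an", "an_lo", "an_hi", "af", "af_lo", "af_hi",
               "component_deaths", "af_in_component")]
  utils::write.csv(af, file.path(dir, "attribution.csv"), row.names = FALSE)
  invisible(dir)
}
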