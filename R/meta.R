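#' Multivariate random-effects meta-analysis
#'
#' Fits the marginal model y_i ~ N(X_i beta, S_i + Psi) across studies
#' (locations) by maximizing the restricted (default) or full likelihood
#' over beta and the between-study covariance Psi. Psi is parameterized
#' to stay positive semi-definite: through its Cholesky factor
#' ("unstructured") or through log standard deviations ("diagonal",
#' recommended for high-dimensional outcomes pooled over few studies).
#' With an optional scalar meta-predictor u_i the fixed design is
#' X_i = [I, u_i I].
#'
#' @param y k x p matrix (or list of p-vectors) of study estimates.
#' @param S list of k within-study p x p covariance matrices.
#' @param predictors optional numeric vector of length k (a single
#'   location-level meta-predictor).
#' @param method "REML" or "ML".
#' @param psi_struct "diagonal" or "unstructured".
#' @param Psi_fixed optional p x p matrix: hold the between-study
#'   covariance fixed at this value instead of estimating it (Psi = 0
#'   gives the fixed-effects inverse-variance pooled estimate).
#' @return list of class `meta_fit`: `beta`, `vcov` (of beta), `Psi`,
#'   `y`, `S`, `X` (list of fixed designs), `method`, `converged`,
#'   `i2_summary`, `logLik`.
#' @export
mvmeta_re <- function(y, S, predictors = NULL, method = c("REML", "ML"),
                      psi_struct = c("diagonal", "unstructured"),
                      Psi_fixed = NULL) {
  method <- match.arg(method); psi_struct <- match.arg(psi_struct)
  if (is.list(y)) y <- do.call(rbind, y)
  y <- as.matrix(y)
  k <- nrow(y); p <- ncol(y)
  stopifnot(length(S) == k, all(vapply(S, nrow, 1L) == p))
  X <- make_meta_design(k, p, predictors)
  q <- ncol(X[[1]])

  if (k == 1L && is.null(predictors)) {
    out <- list(beta = drop(y[1, ]), vcov = S[[1]], Psi = matrix(0, p, p),
                y = y, S = S, X = X, method = method, converged = TRUE,
                i2_summary = 0, logLik = NA_real_)
    class(out) <- "meta_fit"
    return(out)
  }

  par2psi <- function(par) {
    if (psi_struct == "diagonal") {
      diag(exp(2 * par), p, p)
    } else {
      Lm <- matrix(0, p, p)
      Lm[lower.tri(Lm)] <- par[-seq_len(p)]
      diag(Lm) <- exp(par[seq_len(p)])
      Lm %*% t(Lm)
    }
  }
  npar <- if (psi_struct == "diagonal") p else p * (p + 1) / 2

  profile <- function(Psi) {
    A <- matrix(0, q, q); b <- numeric(q)
    logdet <- 0; Ws <- vector("list", k)
    for (i in seq_len(k)) {
      V <- S[[i]] + Psi
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      W <- chol2inv(ch)
      Ws[[i]] <- W
      logdet <- logdet + 2 * sum(log(diag(ch)))
      A <- A + crossprod(X[[i]], W %*% X[[i]])
      b <- b + crossprod(X[[i]], W %*% y[i, ])
    }
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(NULL)
    beta <- drop(chol2inv(chA) %*% b)
    quad <- 0
    for (i in seq_len(k)) {
      r <- y[i, ] - drop(X[[i]] %*% beta)
      quad <- quad + drop(crossprod(r, Ws[[i]] %*% r))
    }
    nll <- 0.5 * (logdet + quad)
    if (method == "REML") nll <- nll + 0.5 * 2 * sum(log(diag(chA)))
    list(nll = nll, beta = beta, vcov_beta = chol2inv(chA))
  }
  if (!is.null(Psi_fixed)) {
    pr <- profile(Psi_fixed)
    if (is.null(pr)) stop("singular covariance with the fixed Psi")
    mean_S <- Reduce(`+`, lapply(S, diag)) / k
    out <- list(beta = pr$beta, vcov = pr$vcov_beta, Psi = Psi_fixed,
                y = y, S = S, X = X, method = method, converged = TRUE,
                i2_summary = mean(diag(Psi_fixed) /
                                    (diag(Psi_fixed) + mean_S)),
                logLik = -pr$nll)
    class(out) <- "meta_fit"
    return(out)
  }

  obj <- function(par) {
    pr <- profile(par2psi(par))
    if (is.null(pr) || !is.finite(pr$nll)) return(1e10)
    pr$nll
  }

  # start: between-study variance at a fraction of the raw spread
  raw_sd <- apply(y, 2, stats::sd)
  raw_sd[!is.finite(raw_sd) | raw_sd <= 0] <- 1e-3
  start <- if (psi_struct == "diagonal") log(raw_sd / 2 + 1e-6) else
    c(log(raw_sd / 2 + 1e-6), rep(0, npar - p))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  Psi <- par2psi(opt$par)
  pr <- profile(Psi)
  mean_S <- Reduce(`+`, lapply(S, diag)) / k
  i2 <- mean(diag(Psi) / (diag(Psi) + mean_S))
  out <- list(beta = pr$beta, vcov = pr$vcov_beta, Psi = Psi, y = y, S = S,
              X = X, method = method, converged = opt$convergence == 0,
              i2_summary = i2, logLik = -pr$nll)
  class(out) <- "meta_fit"
  out
}

make_meta_design <- function(k, p, predictors) {
  if (is.null(predictors)) return(rep(list(diag(p)), k))
  stopifnot(length(predictors) == k)
  lapply(predictors, function(u) cbind(diag(p), u * diag(p)))
}

#' Best linear unbiased predictions from a meta-analysis fit
#'
#' BLUP_i = X_i beta + Psi (S_i + Psi)^-1 (y_i - X_i beta): the location
#' estimate shrunk toward the pooled mean in proportion to its
#' within-location uncertainty. The BLUP covariance accounts for both
#' the conditional random-effect variance and the uncertainty in beta.
#'
#' @param meta a `meta_fit`.
#' @return list per study with `coef` and `vcov`.
#' @export
compute_blups <- function(meta) {
  k <- nrow(meta$y)
  lapply(seq_len(k), function(i) {
    V <- meta$S[[i]] + meta$Psi
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular within+between covariance for study ", i))
    W <- chol2inv(ch)
    Xi <- meta$X[[i]]
    fitted <- drop(Xi %*% meta$beta)
    G <- meta$Psi %*% W
    blup <- fitted + drop(G %*% (meta$y[i, ] - fitted))
    H <- Xi - G %*% Xi
    vc <- meta$Psi - G %*% meta$Psi + H %*% meta$vcov %*% t(H)
    vc <- (vc + t(vc)) / 2
    list(coef = blup, vcov = vc)
  })
}

#' Repeated-measures test of curve differences across TV quartiles
#'
#' Stacks each location's four reduced quartile curves as one correlated
#' outcome (carrying the cross-quartile covariance), pools them by
#' random-effects multivariate meta-analysis with the quartile indicator
#' as the only predictor (equivalently, pooled stacked means), and Wald
#' tests that all quartile-contrast coefficients (Q2-Q1, Q3-Q1, Q4-Q1 on
#' the temperature basis) are jointly zero; df = 3 * var_df.
#'
#' @param curvesets list of `quartile_curves` (one per location).
#' @param psi_struct between-location covariance structure.
#' @return list with `statistic`, `df`, `p_value`, and the pooled
#'   `meta` fit.
#' @export
test_quartile_difference <- function(curvesets, psi_struct = "diagonal") {
  vd <- curvesets[[1]]$var_df
  y <- t(vapply(curvesets, function(cs) cs$coef, numeric(4 * vd)))
  S <- lapply(curvesets, function(cs) cs$vcov)
  meta <- mvmeta_re(y, S, psi_struct = psi_struct)
  L <- matrix(0, 3 * vd, 4 * vd)
  for (m in 1:3) {
    rows <- (m - 1L) * vd + seq_len(vd)
    L[rows, seq_len(vd)] <- -diag(vd)
    L[rows, m * vd + seq_len(vd)] <- diag(vd)
  }
  est <- drop(L %*% meta$beta)
  Vc <- L %*% meta$vcov %*% t(L)
  stat <- drop(crossprod(est, solve(Vc, est)))
  df <- 3L * vd
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), meta = meta)
}

#' Pointwise fixed-effects test of the Q4 - Q1 risk difference
#'
#' At a given temperature percentile, each location contributes its
#' Q4 - Q1 cumulative log-RR difference (evaluated at the location's own
#' temperature for that percentile, relative to a common reference
#' percentile) with a delta-method variance carrying the cross-quartile
#' covariance. Differences are pooled by fixed-effects inverse-variance
#' weighting - appropriate because the per-location quartile estimates
#' come from the same sample - and tested with a two-sided z-test.
#'
#' @param curvesets list of `quartile_curves` for one country.
#' @param percentile temperature percentile (0-100) at which to test.
#' @param center_percentile reference percentile for the difference.
#' @return list with `diff` (pooled log-RR difference), `se`, `z`,
#'   `p_value`.
#' @export
pointwise_q1q4_test <- function(curvesets, percentile,
                                center_percentile = 50) {
  ests <- vars <- numeric(length(curvesets))
  degen <- logical(length(curvesets))
  for (i in seq_along(curvesets)) {
    cs <- curvesets[[i]]
    x <- stats::quantile(cs$warm_temps, percentile / 100, type = 7)
    cx <- stats::quantile(cs$warm_temps, center_percentile / 100, type = 7)
    d <- drop(var_basis(cs$spec, x) - var_basis(cs$spec, cx))
    degen[i] <- max(abs(d)) < 1e-10
    m <- numeric(4 * cs$var_df)
    m[quartile_block(cs, 1L)] <- -d
    m[quartile_block(cs, 4L)] <- d
    ests[i] <- sum(m * cs$coef)
    vars[i] <- drop(crossprod(m, cs$vcov %*% m))
  }
  if (all(degen))   # evaluation point coincides with the reference
    return(list(diff = 0, se = 0, z = 0, p_value = 1))
  if (any(vars <= 0)) stop("nonpositive variance in pointwise contrast")
  wgt <- 1 / vars
  pooled <- sum(wgt * ests) / sum(wgt)
  se <- sqrt(1 / sum(wgt))
  z <- pooled / se
  list(diff = pooled, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' TV-sensitive heat threshold (TVST) for one country
#'
#' Scans a grid of temperature percentiles and applies the pointwise
#' Q4-vs-Q1 fixed-effects test at each. The TVST is the smallest grid
#' percentile from which the test rejects at `alpha` at that percentile
#' and every higher grid percentile (a run of rejections reaching the
#' top of the grid); if no such percentile exists the TVST is
#' unidentified and the caller applies the cross-country fallback.
#'
#' @param curvesets list of `quartile_curves` for the country.
#' @param grid increasing percentiles to scan (the pipeline uses integer
#'   percentiles from the pooled MMT percentile to 100).
#' @param alpha significance level.
#' @param center_percentile reference percentile for the differences.
#' @return list of class `tvst_result`: `identified`,
#'   `tvst_percentile` (NA if unidentified), `p_values`, `grid`.
#' @export
find_tvst <- function(curvesets, grid = 75:100, alpha = 0.05,
                      center_percentile = 50) {
  if (!length(grid)) stop("empty percentile grid")
  pv <- vapply(grid, function(p)
    pointwise_q1q4_test(curvesets, p, center_percentile)$p_value, numeric(1))
  rej <- pv < alpha
  tvst <- NA_real_
  if (all(rej)) {
    tvst <- grid[1]
  } else if (rej[length(rej)]) {
    last_fail <- max(which(!rej))
    if (last_fail < length(rej)) tvst <- grid[last_fail + 1L]
  }
  structure(list(identified = !is.na(tvst), tvst_percentile = tvst,
                 p_values = pv, grid = grid),
            class = "tvst_result")
}

#' TVST table across countries with the mean-percentile fallback
#'
#' Countries without an identifiable TVST receive the arithmetic mean of
#' the identified countries' TVST percentiles (the fallback the primary
#' analysis applies when the pointwise contrast never stabilizes above
#' the detection grid).
#'
#' @param tvst_by_country named list of `tvst_result`.
#' @return data frame with `country_id`, `identified`,
#'   `tvst_percentile` (fallback-filled), `own_percentile`.
#' @export
tvst_table <- function(tvst_by_country) {
  own <- vapply(tvst_by_country, function(r) r$tvst_percentile, numeric(1))
  idf <- vapply(tvst_by_country, function(r) r$identified, logical(1))
  fallback <- if (any(idf)) mean(own[idf]) else NA_real_
  filled <- ifelse(idf, own, fallback)
  data.frame(country_id = names(tvst_by_country), identified = idf,
             tvst_percentile = filled, own_percentile = own,
             row.names = NULL)
}
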