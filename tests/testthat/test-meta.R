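test_that("single-study pooling returns the input with zero heterogeneity", {
  y <- matrix(c(0.2, -0.1, 0.4), 1)
  S <- list(diag(c(0.01, 0.02, 0.03)))
  m <- mvmeta_re(y, S)
  expect_equal(m$beta, drop(y))
  expect_equal(m$vcov, S[[1]])
  expect_equal(m$Psi, matrix(0, 3, 3))
})

test_that("identical studies pool to the common estimate with Psi ~ 0", {
  y <- matrix(rep(c(0.3, -0.2), each = 6), 6)
  S <- rep(list(diag(0.05, 2)), 6)
  m <- mvmeta_re(y, S)
  expect_equal(m$beta, c(0.3, -0.2), tolerance = 1e-6)
  expect_lt(max(diag(m$Psi)), 1e-4)
  b <- compute_blups(m)
  for (i in 1:6) expect_equal(b[[i]]$coef, m$beta, tolerance = 1e-4)
})

test_that("univariate REML agrees with metafor and recovers tau^2", {
  skip_if_not_installed("metafor")
  set.seed(42)
  k <- 20
  vi <- runif(k, 0.005, 0.02)
  yi <- rnorm(k, 0.5, sqrt(0.04 + vi))
  ours <- mvmeta_re(matrix(yi, k), lapply(vi, function(v) matrix(v, 1, 1)))
  ref <- metafor::rma(yi, vi, method = "REML")
  expect_equal(drop(ours$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(ours$Psi[1, 1], ref$tau2, tolerance = 1e-3)
  expect_equal(sqrt(ours$vcov[1, 1]), unname(ref$se), tolerance = 1e-3)
})

test_that("REML recovers a known between-study variance on average", {
  set.seed(7)
  reps <- 200; k <- 20; tau2 <- 0.04; vi <- 0.01
  est <- replicate(reps, {
    theta <- rnorm(k, 1, sqrt(tau2))
    yi <- rnorm(k, theta, sqrt(vi))
    mvmeta_re(matrix(yi, k), rep(list(matrix(vi, 1, 1)), k))$Psi[1, 1]
  })
  se_mc <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - tau2), 4 * se_mc)
})

test_that("pooling with Psi fixed at 0 is the fixed-effects estimate", {
  set.seed(13)
  k <- 8
  yi <- rnorm(k, 0.2, 0.1)
  vi <- runif(k, 0.005, 0.03)
  m <- mvmeta_re(matrix(yi, k), lapply(vi, function(v) matrix(v, 1, 1)),
                 Psi_fixed = matrix(0, 1, 1))
  fe <- sum(yi / vi) / sum(1 / vi)
  expect_equal(drop(m$beta), fe, tolerance = 1e-10)
  expect_equal(m$vcov[1, 1], 1 / sum(1 / vi), tolerance = 1e-10)
})

test_that("BLUPs shrink between the study estimate and the pool", {
  # hand case: y = 2, pooled = 1, S = Psi -> BLUP = 1.5
  m <- structure(list(beta = 1, vcov = matrix(0, 1, 1),
                      Psi = matrix(0.3, 1, 1), y = matrix(2, 1),
                      S = list(matrix(0.3, 1, 1)),
                      X = list(diag(1)), method = "REML", converged = TRUE),
                 class = "meta_fit")
  expect_equal(compute_blups(m)[[1]]$coef, 1.5)

  # Psi = 0 -> full shrinkage to the pool
  m$Psi <- matrix(0, 1, 1)
  expect_equal(compute_blups(m)[[1]]$coef, 1)

  # S -> 0 -> no shrinkage
  m$Psi <- matrix(0.3, 1, 1); m$S <- list(matrix(1e-12, 1, 1))
  expect_equal(compute_blups(m)[[1]]$coef, 2, tolerance = 1e-6)

  # componentwise betweenness in a random multivariate example
  set.seed(5)
  y <- matrix(rnorm(8, 0.3, 0.3), 4)
  S <- rep(list(diag(0.02, 2)), 4)
  mf <- mvmeta_re(y, S)
  bl <- compute_blups(mf)
  for (i in 1:4) {
    lo <- pmin(y[i, ], mf$beta) - 1e-8
    hi <- pmax(y[i, ], mf$beta) + 1e-8
    expect_true(all(bl[[i]]$coef >= lo & bl[[i]]$coef <= hi))
  }
})

test_that("quartile-difference Wald test is exact under the null identity", {
  spec <- toy_spec()
  vd <- spec$var_df
  base <- c(0.05, 0.1, 0.3)
  cs <- lapply(1:5, function(i)
    fake_curves(rep(base, 4), diag(0.01, 4 * vd), spec,
                location_id = paste0("l", i)))
  res <- test_quartile_difference(cs)
  expect_equal(res$statistic, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_equal(res$df, 3 * vd)
})

test_that("pointwise Q1-vs-Q4 pooling matches hand inverse-variance math", {
  spec <- toy_spec()
  vd <- spec$var_df
  wt <- seq(5, 30, length.out = 501)
  x <- unname(quantile(wt, 0.9, type = 7))
  cx <- unname(quantile(wt, 0.5, type = 7))
  d <- drop(ns_basis(x, spec$var_knots, spec$var_boundary) -
              ns_basis(cx, spec$var_knots, spec$var_boundary))
  m <- c(-d, numeric(2 * vd), d)

  mk <- function(diff, var) {
    coef <- numeric(4 * vd)
    coef[3 * vd + 1:vd] <- diff * d / sum(d^2)   # d . coefQ4 = diff
    u <- m / sum(m * m)
    fake_curves(coef, var * outer(u, u), spec, warm_temps = wt)
  }
  # identical Q1/Q4 curves -> z = 0, p = 1
  same <- fake_curves(numeric(4 * vd), diag(1e-4, 4 * vd), spec,
                      warm_temps = wt)
  r0 <- pointwise_q1q4_test(list(same), 90)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)

  # one location: test equals the single-location Wald z
  one <- mk(0.2, 0.01)
  r1 <- pointwise_q1q4_test(list(one), 90)
  expect_equal(r1$diff, 0.2, tolerance = 1e-10)
  expect_equal(r1$z, 0.2 / 0.1, tolerance = 1e-8)

  # two locations, diffs 0.2 (var 0.01) and 0.0 (var 0.04):
  # pooled = 0.16, z = 1.789
  r2 <- pointwise_q1q4_test(list(mk(0.2, 0.01), mk(0.0, 0.04)), 90)
  expect_equal(r2$diff, 0.16, tolerance = 1e-10)
  expect_equal(round(r2$z, 3), 1.789)
})

test_that("TVST follows the run-of-rejections rule and the mean fallback", {
  spec <- toy_spec()
  vd <- spec$var_df
  wt <- seq(5, 30, length.out = 501)

  # identical curves everywhere -> unidentified
  same <- fake_curves(numeric(4 * vd), diag(1e-4, 4 * vd), spec,
                      warm_temps = wt)
  r <- find_tvst(list(same), grid = 75:100)
  expect_false(r$identified)
  expect_true(is.na(r$tvst_percentile))

  # constructed divergence: Q4 - Q1 grows with temperature; with the
  # chosen noise the z statistic crosses 1.96 inside the grid; the
  # reported TVST must match an independent scan of the p-values
  set.seed(2)
  coef <- numeric(4 * vd)
  coef[3 * vd + 1:vd] <- reduce_overall(rep(0.02, vd * spec$lag_df),
                                        NULL, spec)$coef
  cs <- fake_curves(coef, diag(2e-4, 4 * vd), spec, warm_temps = wt)
  res <- find_tvst(list(cs), grid = 75:100, alpha = 0.05)
  rej <- res$p_values < 0.05
  oracle <- NA_real_
  for (i in rev(seq_along(rej))) {
    if (!rej[i]) break
    oracle <- res$grid[i]
  }
  expect_equal(res$tvst_percentile, oracle)
  expect_true(res$identified)
  # all points from the TVST upward reject; the point just below fails
  from <- match(res$tvst_percentile, res$grid)
  expect_true(all(rej[from:length(rej)]))
  if (from > 1) expect_false(rej[from - 1])

  # fallback: mean of identified TVSTs fills unidentified countries
  r92 <- r; r92$identified <- TRUE; r92$tvst_percentile <- 92
  r96 <- r; r96$identified <- TRUE; r96$tvst_percentile <- 96
  tab <- tvst_table(list(a = r92, b = r96, c = r))
  expect_equal(tab$tvst_percentile[tab$country_id == "c"], 94)
  expect_false(tab$identified[tab$country_id == "c"])
})
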