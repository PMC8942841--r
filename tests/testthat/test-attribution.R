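test_that("MMT search matches a finer-grid oracle and boundary rules", {
  spec <- toy_spec()
  temps <- seq(5, 30, length.out = 2001)
  set.seed(4)
  # a curve with an interior minimum: fit the basis to a parabola
  grid <- seq(5, 30, by = 0.05)
  B <- ns_basis(grid, spec$var_knots, spec$var_boundary)
  target <- (grid - 19)^2 / 100
  co <- unname(coef(lm(target ~ B))[-1])   # intercept shift leaves argmin
  m <- find_mmt(co, spec, temps)
  # oracle: exhaustive 0.01-degree grid search on the same curve
  fine <- seq(quantile(temps, 0.01, type = 7), quantile(temps, 0.99, type = 7),
              by = 0.01)
  oracle <- fine[which.min(drop(ns_basis(fine, spec$var_knots,
                                         spec$var_boundary) %*% co))]
  expect_lt(abs(m$temp - oracle), 0.1 + 1e-9)
  expect_lt(abs(m$temp - 19), 0.5)          # near the parabola minimum

  # monotone increasing curve: MMT at the lower search bound
  inc <- unname(coef(lm(I(grid / 10) ~ 0 + B)))
  m2 <- find_mmt(inc, spec, temps)
  expect_equal(m2$temp, m2$range[1])
  expect_error(find_mmt(co, spec, temps, c(50, 50)), "search_percentiles")
})

test_that("attributable deaths follow the backward formula exactly", {
  spec <- toy_spec()
  vd <- spec$var_df
  # coefficient block giving RR(x*) = 2 at one temperature
  xstar <- 27; mmt <- 18
  d <- drop(ns_basis(xstar, spec$var_knots, spec$var_boundary) -
              ns_basis(mmt, spec$var_knots, spec$var_boundary))
  coef_q1 <- log(2) * d / sum(d^2)
  coef <- c(coef_q1, numeric(3 * vd))
  cur <- fake_curves(coef, matrix(0, 4 * vd, 4 * vd), spec)

  n <- 30
  tmean <- rep(10, n); tmean[15] <- xstar
  deaths <- rep(10, n)
  s <- toy_series(n, deaths, tmean)
  ex <- structure(list(tv = rep(1, n),
                       tv_quartile = factor(rep("Q1", n),
                                            levels = paste0("Q", 1:4)),
                       warm_season = rep(TRUE, n),
                       cutpoints = c(1, 1, 1), warm_months = 7:10),
                  class = "exposure_table")
  # one qualifying day with RR = 2 and 10 deaths -> AN = 5 exactly
  expect_equal(attributable_deaths(s, ex, cur, mmt, 1), 5, tolerance = 1e-12)
  # RR identically 1 -> AN = 0
  cur0 <- fake_curves(numeric(4 * vd), matrix(0, 4 * vd, 4 * vd), spec)
  expect_equal(attributable_deaths(s, ex, cur0, mmt, 1), 0)

  # 30-day toy series against a day-by-day spreadsheet oracle
  set.seed(8)
  tmean2 <- runif(n, 12, 29)
  deaths2 <- rpois(n, 20)
  s2 <- toy_series(n, deaths2, tmean2)
  an <- attributable_deaths(s2, ex, cur, mmt, 1)
  oracle <- 0
  for (t in 1:n) {
    if (tmean2[t] > mmt) {
      rr <- exp(sum((ns_basis(tmean2[t], spec$var_knots, spec$var_boundary) -
                       ns_basis(mmt, spec$var_knots, spec$var_boundary)) *
                      coef_q1))
      oracle <- oracle + deaths2[t] * (1 - 1 / rr)
    }
  }
  expect_equal(an, oracle, tolerance = 1e-10)

  # doubling deaths doubles AN (AF invariance through RR only)
  s3 <- toy_series(n, 2 * deaths2, tmean2)
  expect_equal(attributable_deaths(s3, ex, cur, mmt, 1), 2 * an,
               tolerance = 1e-10)

  # raising the TVST cannot increase the above-TVST component
  an_above <- function(tvst)
    attributable_deaths(s2, ex, cur, mmt, 1, range = c(tvst, Inf))
  expect_true(an_above(25) >= an_above(27))
  expect_equal(an_above(max(tmean2)), 0)   # empty interval above the max
})

test_that("attributable fractions are simple ratios", {
  expect_equal(unname(af_components(c(between = 12, above = 8), 1000)),
               c(1.2, 0.8, 2.0))
  expect_equal(unname(af_components(c(a = 0), 500)), c(0, 0))
  expect_error(af_components(c(a = 1), 0), "positive")
})

test_that("Monte Carlo empirical CIs are seeded and collapse without noise", {
  spec <- toy_spec()
  vd <- spec$var_df
  set.seed(14)
  n <- 120
  tmean <- runif(n, 10, 29)
  deaths <- rpois(n, 15)
  s <- toy_series(n, deaths, tmean)
  qlab <- factor(paste0("Q", sample(1:4, n, TRUE)),
                 levels = paste0("Q", 1:4))
  ex <- structure(list(tv = rep(1, n), tv_quartile = qlab,
                       warm_season = rep(TRUE, n),
                       cutpoints = c(1, 2, 3), warm_months = 7:10),
                  class = "exposure_table")
  coef <- rep(c(0.02, 0.05, 0.1), 4) * rep(1:4, each = vd)
  mmt <- list(temp = 15, percentile = 40)

  # zero covariance: eCI equals the point estimate exactly
  cur0 <- fake_curves(coef, matrix(0, 4 * vd, 4 * vd), spec)
  r0 <- attribute_location(s, ex, cur0, tvst_temp = 25, mmt = mmt,
                           n_draws = 50, seed = 3)
  expect_equal(r0$table$an_lo, r0$table$an, tolerance = 1e-12)
  expect_equal(r0$table$an_hi, r0$table$an, tolerance = 1e-12)

  # same seed twice: identical CIs; different seed: different CIs
  cur <- fake_curves(coef, diag(0.005, 4 * vd), spec)
  r1 <- attribute_location(s, ex, cur, 25, mmt, n_draws = 100, seed = 7)
  r2 <- attribute_location(s, ex, cur, 25, mmt, n_draws = 100, seed = 7)
  expect_identical(r1$table, r2$table)
  r3 <- attribute_location(s, ex, cur, 25, mmt, n_draws = 100, seed = 8)
  expect_false(identical(r1$table$an_lo, r3$table$an_lo))

  # components sum to the total heat AN
  tot <- r1$table$an[r1$table$component == "total"]
  parts <- tapply(r1$table$an[r1$table$component != "total"],
                  r1$table$quartile[r1$table$component != "total"], sum)
  expect_equal(as.numeric(parts[paste0("Q", 1:4)]), tot, tolerance = 1e-10)
  expect_true(all(r1$table$an_lo <= r1$table$an_hi))
  expect_error(attribute_location(s, ex, cur, 25, mmt, n_draws = 0), "n_draws")
})

test_that("aggregation sums draws by index and preserves identities", {
  spec <- toy_spec()
  vd <- spec$var_df
  set.seed(20)
  mk_loc <- function(seed, lam) {
    n <- 100
    tmean <- runif(n, 12, 29)
    deaths <- rpois(n, lam)
    s <- toy_series(n, deaths, tmean)
    qlab <- factor(paste0("Q", sample(1:4, n, TRUE)),
                   levels = paste0("Q", 1:4))
    ex <- structure(list(tv = rep(1, n), tv_quartile = qlab,
                         warm_season = rep(TRUE, n),
                         cutpoints = c(1, 2, 3), warm_months = 7:10),
                    class = "exposure_table")
    cur <- fake_curves(rep(0.05, 4 * vd), diag(0.004, 4 * vd), spec)
    attribute_location(s, ex, cur, 26, list(temp = 16, percentile = 30),
                       n_draws = 80, seed = seed)
  }
  a <- mk_loc(1, 10); b <- mk_loc(2, 30)

  # single-member group is the member
  solo <- aggregate_attribution(list(a), scope = "solo")
  expect_equal(solo$table$an, a$table$an)
  expect_equal(solo$table$af, a$table$af)

  g <- aggregate_attribution(list(a, b), scope = "pair")
  expect_equal(g$total_deaths, a$total_deaths + b$total_deaths)
  expect_equal(g$table$an, a$table$an + b$table$an, tolerance = 1e-10)
  # aggregated eCI equals percentiles of the summed per-draw ANs
  sum_draws <- a$draws + b$draws
  q1b <- sum_draws[, "Q1_between"]
  row <- g$table$quartile == "Q1" & g$table$component == "between"
  expect_equal(g$table$an_lo[row],
               unname(quantile(q1b, 0.025, type = 7)), tolerance = 1e-12)
  expect_equal(g$table$an_hi[row],
               unname(quantile(q1b, 0.975, type = 7)), tolerance = 1e-12)
  # worked ratio: AN 5 + 15 over totals 500 + 1500 -> AF = 1%
  expect_equal(100 * (5 + 15) / (500 + 1500), 1)

  bad <- mk_loc(3, 10); bad$n_draws <- 40; bad$draws <- bad$draws[1:40, ]
  expect_error(aggregate_attribution(list(a, bad)), "draw counts")
})
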