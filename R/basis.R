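#' Natural cubic spline basis with fixed knots
#'
#' Wraps [splines::ns()] with explicit interior and boundary knots and no
#' intercept column, so the basis has dimension #interior_knots + 1 and
#' is linear beyond the boundary knots. NA inputs yield NA rows.
#'
#' @param x evaluation points.
#' @param interior_knots knot values strictly inside `boundary`.
#' @param boundary length-2 boundary knot pair.
#' @return matrix with `length(interior_knots) + 1` columns.
#' @export
ns_basis <- function(x, interior_knots, boundary) {
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2])
  if (any(interior_knots <= boundary[1]) || any(interior_knots >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary knots")
  df <- length(interior_knots) + 1L
  out <- matrix(NA_real_, length(x), df)
  ok <- !is.na(x)
  if (any(ok))
    out[ok, ] <- splines::ns(x[ok], knots = interior_knots,
                             Boundary.knots = boundary, intercept = FALSE)
  out
}

#' Log-spaced interior knots for the lag dimension
#'
#' Knots at exp(k/(n_knots+1) * log(lag_max)) for k = 1..n_knots, i.e.
#' equally spaced on the log-lag scale anchored at lag 1 (log 0 being
#' undefined) and lag_max.
#'
#' @param lag_max maximum lag (>= 2).
#' @param n_knots number of interior knots (>= 1).
#' @return increasing knot values in (1, lag_max).
#' @examples
#' log_lag_knots(10, 2)  # 10^(1/3), 10^(2/3) = 2.1544, 4.6416
#' @export
log_lag_knots <- function(lag_max, n_knots = 2L) {
  stopifnot(lag_max >= 2, n_knots >= 1)
  exp(seq_len(n_knots) / (n_knots + 1) * log(lag_max))
}

#' Cross-basis specification
#'
#' Holds the bidimensional spline parameterization: a natural cubic
#' spline along temperature (no intercept; dimension var_df =
#' #var_knots + 1) and a natural cubic spline along lag 0..lag_max (with
#' intercept; dimension lag_df = #lag_knots + 2), plus a centering value
#' for relative risks.
#'
#' @param var_knots interior temperature knots, degrees C.
#' @param var_boundary boundary temperature pair.
#' @param lag_max maximum lag in days.
#' @param lag_knots interior lag knots; default [log_lag_knots()] with 2
#'   knots.
#' @param center reference temperature for RR (re-set to the MMT after
#'   pooling).
#' @return list of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(var_knots, var_boundary, lag_max = 10L,
                            lag_knots = log_lag_knots(lag_max, 2L),
                            center = mean(var_boundary)) {
  stopifnot(var_boundary[1] < var_boundary[2],
            all(var_knots > var_boundary[1]), all(var_knots < var_boundary[2]),
            all(lag_knots > 0), all(lag_knots < lag_max))
  spec <- list(var_knots = as.numeric(var_knots),
               var_boundary = as.numeric(var_boundary),
               lag_max = as.integer(lag_max),
               lag_knots = as.numeric(lag_knots),
               var_df = length(var_knots) + 1L,
               lag_df = length(lag_knots) + 2L,
               center = center)
  class(spec) <- "crossbasis_spec"
  spec
}

# temperature basis evaluated at x (rows) for a spec
var_basis <- function(spec, x) {
  ns_basis(x, spec$var_knots, spec$var_boundary)
}

# lag basis evaluated on the integer lags 0..lag_max (with intercept)
lag_basis <- function(spec) {
  lags <- 0:spec$lag_max
  unclass(splines::ns(lags, knots = spec$lag_knots,
                      Boundary.knots = c(0, spec$lag_max), intercept = TRUE))
}

#' Build the tensor-product cross-basis matrix
#'
#' Column (j, k) at row t equals sum over lags l = 0..lag_max of
#' B_j(tmean[t-l]) * C_k(l), where B is the temperature natural-spline
#' basis and C the lag natural-spline basis (with intercept). Columns are
#' ordered with the temperature index j varying fastest within each lag
#' index k. Rows whose lag window extends before the series start or
#' contains a missing temperature are NA.
#'
#' @param tmean daily mean temperature series.
#' @param spec a `crossbasis_spec`.
#' @return n x (var_df * lag_df) matrix with the spec attached as
#'   attribute `spec`.
#' @export
build_crossbasis <- function(tmean, spec) {
  n <- length(tmean)
  L <- spec$lag_max
  if (n <= L) stop("series length must exceed lag_max")
  C <- lag_basis(spec)                      # (L+1) x lag_df
  B <- var_basis(spec, tmean)               # n x var_df
  out <- matrix(0, n, spec$var_df * spec$lag_df)
  bad <- rep(FALSE, n)
  for (l in 0:L) {
    idx <- seq_len(n) - l
    Bl <- matrix(NA_real_, n, spec$var_df)
    valid <- idx >= 1
    Bl[valid, ] <- B[idx[valid], , drop = FALSE]
    bad <- bad | !valid | rowSums(is.na(Bl)) > 0
    Bl[is.na(Bl)] <- 0
    for (k in seq_len(spec$lag_df)) {
      cols <- (k - 1L) * spec$var_df + seq_len(spec$var_df)
      out[, cols] <- out[, cols] + Bl * C[l + 1L, k]
    }
  }
  out[bad, ] <- NA_real_
  attr(out, "spec") <- spec
  out
}

#' Reduce cross-basis coefficients to the overall cumulative association
#'
#' Sums the lag-specific contributions over the whole lag window: reduced
#' coefficient j = sum_k coef[j,k] * (sum_l C_k(l)). The reduced vector
#' lives on the temperature basis alone; the cumulative log-RR at
#' temperature x relative to center c is sum_j reduced_j (B_j(x) -
#' B_j(c)). The covariance maps through the same linear map M as
#' M Sigma M'.
#'
#' @param coefs cross-basis coefficient vector (length var_df * lag_df).
#' @param vcov conformable symmetric covariance matrix (or NULL).
#' @param spec the `crossbasis_spec` used to build the matrix.
#' @return list with `coef` (length var_df), `vcov`, and the map `M`.
#' @export
reduce_overall <- function(coefs, vcov = NULL, spec) {
  p <- spec$var_df * spec$lag_df
  stopifnot(length(coefs) == p)
  M <- reduction_map(spec)
  out <- list(coef = drop(M %*% coefs), M = M)
  if (!is.null(vcov)) {
    stopifnot(nrow(vcov) == p, ncol(vcov) == p)
    if (max(abs(vcov - t(vcov))) > 1e-6 * max(1, max(abs(vcov))))
      stop("vcov is not symmetric")
    out$vcov <- M %*% vcov %*% t(M)
  }
  out
}

# the var_df x (var_df*lag_df) linear map of reduce_overall
reduction_map <- function(spec) {
  s <- colSums(lag_basis(spec))             # sum over lags of each C_k
  M <- matrix(0, spec$var_df, spec$var_df * spec$lag_df)
  for (k in seq_len(spec$lag_df)) {
    cols <- (k - 1L) * spec$var_df + seq_len(spec$var_df)
    M[cbind(seq_len(spec$var_df), cols)] <- s[k]
  }
  M
}

#' Cumulative log-relative-risk curve from reduced coefficients
#'
#' @param red_coef reduced coefficient vector (length var_df).
#' @param spec the `crossbasis_spec`.
#' @param x temperatures at which to evaluate.
#' @param center reference temperature; default the spec's center.
#' @return numeric vector of cumulative log-RR values.
#' @export
cumulative_logrr <- function(red_coef, spec, x, center = spec$center) {
  D <- var_basis(spec, x) - matrix(var_basis(spec, center),
                                   length(x), spec$var_df, byrow = TRUE)
  drop(D %*% red_coef)
}
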