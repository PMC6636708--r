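#' Polynomial ordinary least squares with an F-test
#'
#' Centralizes the linear and quadratic fits used throughout the package:
#' a degree-1 or degree-2 polynomial with intercept, an F-test of the full
#' model against the intercept-only model, and (for quadratics) the vertex
#' of the fitted parabola in predictor units.
#'
#' @param x,y numeric vectors of equal length (>= degree + 2); `x` must vary.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return An object of class `"regression_fit"`: a list with
#'   `coefficients` (intercept first), `r_squared` (fraction in [0,1]),
#'   `f_statistic`, `df` (numerator, denominator), `p_value`, `sigma`,
#'   `slope_p_value` (two-sided t-test on the linear term), and `vertex`
#'   (quadratics only; `NA` when the quadratic coefficient is 0).
#' @export
ols_fit <- function(x, y, degree = 1) {
  if (!degree %in% 1:2) stop("`degree` must be 1 or 2", call. = FALSE)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < degree + 2)
    stop(sprintf("need >= %d points for degree %d", degree + 2, degree),
         call. = FALSE)
  if (length(unique(x)) < degree + 1)
    stop("design is rank deficient: too few distinct x values", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- if (degree == 1) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x + I(x^2), data = df)
  if (stats::var(y) == 0) {
    # flat response: R reports 0/0 garbage for r^2; the fit is the constant
    co <- c(y[1L], rep(0, degree))
    return(structure(list(design = c("linear", "quadratic")[degree],
                          coefficients = co, r_squared = 0,
                          f_statistic = 0,
                          df = c(degree, length(x) - degree - 1),
                          p_value = 1, sigma = 0, slope_p_value = 1,
                          vertex = NA_real_, model = fit),
                     class = "regression_fit"))
  }
  sm <- summary(fit)
  co <- unname(stats::coef(fit))
  fstat <- sm$fstatistic
  # a flat response has no F statistic; report 0 with p = 1
  if (is.null(fstat)) fstat <- c(value = 0, numdf = degree,
                                 dendf = length(x) - degree - 1)
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  vertex <- if (degree == 2) {
    if (abs(co[3L]) > 0) -co[2L] / (2 * co[3L]) else NA_real_
  } else NA_real_
  slope_p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2L, 4L]
             else NA_real_
  structure(list(design = c("linear", "quadratic")[degree],
                 coefficients = co,
                 r_squared = if (is.na(sm$r.squared)) 0 else sm$r.squared,
                 f_statistic = unname(fstat[1L]),
                 df = unname(fstat[2:3]),
                 p_value = unname(p),
                 sigma = sm$sigma,
                 slope_p_value = unname(slope_p),
                 vertex = unname(vertex),
                 model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s OLS fit: F_%g,%g = %.4g, r^2 = %.1f%%, p = %.3g\n",
              x$design, x$df[1L], x$df[2L], x$f_statistic,
              100 * x$r_squared, x$p_value))
  cat("coefficients:", format(x$coefficients, digits = 6), "\n")
  if (!is.na(x$vertex)) cat("vertex:", format(x$vertex, digits = 6), "\n")
  invisible(x)
}

#' Diversification rate through time from binned mean diversity
#'
#' Takes millennial-bin mean lineage counts (see [millennial_series()]),
#' converts consecutive bins to per-year rates Delta ln(mean N) / Delta t,
#' and fits a quadratic in time BP.  The vertex of the parabola is the
#' inflection time: before it diversity accumulates at an increasing rate,
#' after it the rate declines.
#'
#' @param millennial data frame with columns `mid_bp` and `mean_n`
#'   (>= 5 bins, all means > 0).
#' @return A list with `fit` (a `"regression_fit"`), `rates` (data frame of
#'   `mid_bp`, `rate`), `vertex_bp`, and `vertex_reliable` (FALSE when the
#'   quadratic term is not significant at 0.05).
#' @export
rate_vs_time <- function(millennial) {
  if (nrow(millennial) < 5) stop("need >= 5 bins", call. = FALSE)
  if (any(millennial$mean_n <= 0))
    stop("non-positive bin means: cannot take logs", call. = FALSE)
  m <- millennial[order(-millennial$mid_bp), , drop = FALSE]
  k <- nrow(m)
  # time runs forward as BP decreases
  dt <- m$mid_bp[-k] - m$mid_bp[-1L]
  rate <- (log(m$mean_n[-1L]) - log(m$mean_n[-k])) / dt
  mid <- (m$mid_bp[-k] + m$mid_bp[-1L]) / 2
  fit <- ols_fit(mid, rate, degree = 2)
  quad_p <- stats::coef(summary(fit$model))["I(x^2)", 4L]
  list(fit = fit, rates = data.frame(mid_bp = mid, rate = rate),
       vertex_bp = fit$vertex,
       vertex_reliable = is.finite(fit$vertex) && !is.na(quad_p) &&
         quad_p < 0.05)
}

#' Diversification rate as a function of standing diversity
#'
#' Fits rate on ln N and (ln N)^2 — the predictor is logged to capture the
#' right skew of clade sizes, the response is not (interval rates can be 0
#' or negative).  When the quadratic coefficient is negative the fitted
#' curve peaks at N* = exp(-b1 / (2 b2)), the diversity at which the
#' diversification rate is maximal.
#'
#' @param rates data frame with columns `n` (>= 1) and `rate` (>= 5 rows).
#' @return A list with `fit`, `peak_n` (NA when undefined), and
#'   `peak_defined` (TRUE iff the quadratic coefficient is < 0).
#' @export
rate_vs_diversity <- function(rates) {
  if (nrow(rates) < 5) stop("need >= 5 points", call. = FALSE)
  if (any(rates$n < 1)) stop("`n` must be >= 1", call. = FALSE)
  fit <- ols_fit(log(rates$n), rates$rate, degree = 2)
  b2 <- fit$coefficients[3L]
  defined <- is.finite(b2) && b2 < 0
  list(fit = fit,
       peak_n = if (defined) exp(fit$vertex) else NA_real_,
       peak_defined = defined)
}

#' Across-family trend of diversification rate with root age
#'
#' Regresses per-family overall rates on family root age.  The default
#' response is ln(r) — an exponential time trend is a straight line on that
#' scale — with `raw_rate` available as an alternative.  Reports the implied
#' percent change in rate per millennium, (e^{|slope| * 1000} - 1) * 100,
#' and the doubling (or halving) time of the rate itself, ln 2 / |slope|.
#'
#' @param estimates a [rate_table()] data frame (one catalog's rows) or any
#'   data frame with columns `r_e` and `root_age_yr`; >= 3 families.
#' @param response `"log_rate"` (default) or `"raw_rate"`.
#' @param catalog when `estimates` has a `catalog` column, which one to use.
#' @return A list with `fit`, `slope` (per year), `percent_per_millennium`,
#'   `rate_doubling_time` (years), `n_used`.
#' @export
across_family_trend <- function(estimates, response = c("log_rate", "raw_rate"),
                                catalog = "ethnologue") {
  response <- match.arg(response)
  df <- estimates
  if ("catalog" %in% names(df)) df <- df[df$catalog == catalog, , drop = FALSE]
  zero <- df$r_e <= 0
  if (any(zero)) {
    warning(sprintf("%d famil%s with r_e <= 0 excluded from the trend",
                    sum(zero), if (sum(zero) == 1) "y" else "ies"),
            call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  if (nrow(df) < 3) stop("need >= 3 families with r_e > 0", call. = FALSE)
  y <- if (response == "log_rate") log(df$r_e) else df$r_e
  fit <- ols_fit(df$root_age_yr, y, degree = 1)
  slope <- fit$coefficients[2L]
  list(fit = fit, slope = slope,
       percent_per_millennium = (exp(abs(slope) * 1000) - 1) * 100,
       rate_doubling_time = if (slope != 0) log(2) / abs(slope) else Inf,
       n_used = nrow(df), response = response)
}

#' Classify density dependence of diversification within a family
#'
#' Regresses the binned interval rates r_b on ln N at each bin's older edge
#' (so the predictor never uses information from inside the interval whose
#' rate is the response).  A slope significantly below 0 at level `alpha`
#' is negative density dependence (rates slow as diversity accumulates,
#' i.e. niche saturation); significantly above 0 is positive density
#' dependence (diversity begets diversity); otherwise the family is
#' consistent with a constant rate (Yule-like exponential growth).
#'
#' @param binned a [binned_rates()] object (or equivalent data frame with
#'   columns `rate` and `ln_n_start`); >= 4 usable bins.
#' @param alpha two-sided significance level.
#' @return An object of class `"density_class"`: list with `class` (one of
#'   `"negative_density_dependence"`, `"positive_density_dependence"`,
#'   `"constant_rate"`), `slope`, `p_value`, `alpha`, `n_bins_used`.
#' @export
classify_density <- function(binned, alpha = 0.05) {
  ok <- is.finite(binned$rate) & is.finite(binned$ln_n_start)
  if (sum(ok) < 4)
    stop("insufficient resolution: fewer than 4 usable bins", call. = FALSE)
  x <- binned$ln_n_start[ok]
  y <- binned$rate[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    slope <- 0
    p <- 1
  } else {
    fit <- ols_fit(x, y, degree = 1)
    slope <- fit$coefficients[2L]
    p <- fit$slope_p_value
  }
  cls <- if (!is.na(p) && p < alpha) {
    if (slope < 0) "negative_density_dependence"
    else "positive_density_dependence"
  } else "constant_rate"
  structure(list(class = cls, slope = slope, p_value = p, alpha = alpha,
                 n_bins_used = sum(ok)),
            class = "density_class")
}

#' @export
print.density_class <- function(x, ...) {
  cat(sprintf("%s (slope %.4g, p = %.3g, alpha = %g, %d bins)\n",
              x$class, x$slope, x$p_value, x$alpha, x$n_bins_used))
  invisible(x)
}
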