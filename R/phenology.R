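#' Double-logistic NDVI model
#'
#' Scaled NDVI as a function of day-of-year for a pixel with spring
#' inflection `xmidS` (day of fastest green-up), spring scale `scalS`
#' (days; smaller = steeper green-up), and the corresponding autumn
#' senescence parameters `xmidA`, `scalA`:
#' \deqn{NDVI(t) = \frac{1}{1+e^{(xmidS-t)/scalS}} -
#'                \frac{1}{1+e^{(xmidA-t)/scalA}}}
#'
#' @param t day-of-year (numeric, may be fractional).
#' @param xmidS,scalS,xmidA,scalA curve parameters (days).
#' @return scaled NDVI in `[0, 1)`.
#' @export
dbl_logistic <- function(t, xmidS, scalS, xmidA, scalA) {
  stats::plogis((t - xmidS) / scalS) - stats::plogis((t - xmidA) / scalA)
}

#' Construct a phenology curve
#'
#' @param xmidS,scalS,xmidA,scalA double-logistic parameters (days).
#' @param fit_rss residual sum of squares of the fit on the scaled-NDVI
#'   scale (0 for curves constructed from known parameters).
#' @return object of class `pheno_curve`.
#' @export
pheno_curve <- function(xmidS, scalS, xmidA = xmidS + 100, scalA = 12,
                        fit_rss = 0) {
  stopifnot(scalS > 0, scalA > 0, xmidS < xmidA)
  structure(list(xmidS = xmidS, scalS = scalS, xmidA = xmidA,
                 scalA = scalA, fit_rss = fit_rss),
            class = "pheno_curve")
}

#' @export
print.pheno_curve <- function(x, ...) {
  cat(sprintf(
    "<pheno_curve> xmidS=%.1f scalS=%.2f xmidA=%.1f scalA=%.2f (rss %.3g)\n",
    x$xmidS, x$scalS, x$xmidA, x$scalA, x$fit_rss))
  invisible(x)
}

#' Rescale an NDVI series to [0, 1]
#'
#' Min-max rescaling so that 1 marks maximum plant biomass for the pixel.
#' Optional winsorization clips values outside the 2nd/98th percentiles
#' before rescaling, guarding against snow/cloud spikes; values are then
#' clamped to the clipped range so a single artifact cannot set the
#' maximum.
#'
#' @param value numeric NDVI values.
#' @param winsorize clip to the `probs` percentiles before rescaling?
#' @param probs length-2 percentile bounds used when `winsorize = TRUE`.
#' @return numeric vector on `[0, 1]`, with attribute `scalable` set to
#'   `FALSE` (and all values `NA`) when the series is constant.
#' @export
scale_ndvi <- function(value, winsorize = FALSE, probs = c(0.02, 0.98)) {
  stopifnot(is.numeric(value), length(value) >= 2)
  v <- value
  if (winsorize) {
    q <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
    v <- pmin(pmax(v, q[1]), q[2])
  }
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    out <- rep(NA_real_, length(v))
    attr(out, "scalable") <- FALSE
    return(out)
  }
  out <- (v - rng[1]) / diff(rng)
  attr(out, "scalable") <- TRUE
  out
}

#' Fit a double-logistic green-up curve to a scaled NDVI series
#'
#' Nonlinear least squares with multi-start initialization: the spring
#' inflection starts at the day of maximum first difference, the autumn
#' inflection at the day of minimum first difference, and the spring scale
#' is tried at several widths because double logistics have local optima.
#'
#' @param day observation days-of-year (>= 8 points spanning spring).
#' @param value scaled NDVI at `day` (see [scale_ndvi()]).
#' @param scalS_starts spring-scale starting values for the multi-start.
#' @return a [pheno_curve()] with `fit_rss` recorded, or `NULL` when the
#'   series has no spring green-up signal or no start converges (the
#'   pixel is flagged missing).
#' @export
fit_double_logistic <- function(day, value, scalS_starts = c(3, 8, 15)) {
  stopifnot(length(day) == length(value), length(day) >= 8)
  ok <- is.finite(day) & is.finite(value)
  day <- day[ok]; value <- value[ok]
  if (length(day) < 8 || diff(range(value)) == 0) return(NULL)
  d1 <- diff(value) / diff(day)
  if (max(d1) <= 0) return(NULL)        # monotone decreasing: no green-up
  xmidS0 <- day[which.max(d1)]
  xmidA0 <- if (min(d1) < 0) day[which.min(d1)] else max(day) - 10
  if (xmidA0 <= xmidS0) xmidA0 <- xmidS0 + diff(range(day)) / 3

  best <- NULL
  for (s0 in scalS_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ dbl_logistic(day, xmidS, scalS, xmidA, scalA),
        start = list(xmidS = xmidS0, scalS = s0, xmidA = xmidA0, scalA = 10),
        lower = c(min(day) - 30, 0.5, min(day) - 30, 0.5),
        upper = c(max(day) + 30, 60, max(day) + 60, 60),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  if (!(p[["xmidS"]] < p[["xmidA"]])) return(NULL)
  pheno_curve(p[["xmidS"]], p[["scalS"]], p[["xmidA"]], p[["scalA"]],
              fit_rss = best$rss)
}

#' Instantaneous Rate of Green-up
#'
#' IRG is the first derivative of the spring logistic component of the
#' fitted double-logistic curve (senescence is excluded: its derivative is
#' negative and would shift peak dates for early-autumn pixels):
#' \deqn{IRG(t) = \frac{e^{(xmidS-t)/scalS}}
#'   {scalS\,(1+e^{(xmidS-t)/scalS})^2}}
#' The maximum, `1/(4 scalS)`, is attained at `t = xmidS`.
#'
#' @param curve a [pheno_curve()].
#' @param t day-of-year (vectorized).
#' @return green-up rate per day (non-negative).
#' @export
irg <- function(curve, t) {
  stats::dlogis((t - curve$xmidS) / curve$scalS) / curve$scalS
}

#' Date of peak IRG
#'
#' The spring-component derivative is maximized at the spring inflection,
#' so the peak-IRG date is `xmidS`.
#'
#' @param curve a [pheno_curve()].
#' @return day-of-year of peak green-up.
#' @export
peak_irg_date <- function(curve) curve$xmidS

#' Loss-in-IRG foraging penalty
#'
#' Mean drop in IRG over the 14 days bracketing the peak (offsets 1..7
#' days before and after), expressed as a percent of peak IRG. Steep,
#' fleeting green-up (small `scalS`) gives a large penalty: a mismatched
#' animal loses more forage quality per day of mismatch where the wave is
#' most rapid.
#'
#' @param curve a [pheno_curve()].
#' @return percent loss in `[0, 100)`.
#' @export
loss_in_irg <- function(curve) {
  pk <- peak_irg_date(curve)
  peak_val <- irg(curve, pk)
  offsets <- c(-7:-1, 1:7)
  mean(peak_val - irg(curve, pk + offsets)) / peak_val * 100
}
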