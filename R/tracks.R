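#' Remove implausible GPS fixes by segment speed
#'
#' Greedy forward pass: walking the track in time order, a fix whose
#' incoming segment speed (from the last retained fix) exceeds the
#' threshold is dropped, and subsequent speeds are measured from the last
#' retained fix. This removes teleporting outliers while keeping the
#' fixes around them, and is idempotent: a cleaned track has no remaining
#' violations.
#'
#' @param track a `deer_track` (or data frame with `t` in days and `x`,
#'   `y` in meters), time-ordered.
#' @param max_kmh speed threshold, km/h (default 10.8, the upper bound of
#'   plausible sustained deer movement).
#' @return the cleaned track, with attributes `removed` (count) and
#'   `removed_fraction`.
#' @export
speed_filter <- function(track, max_kmh = 10.8) {
  stopifnot(nrow(track) >= 2, max_kmh > 0)
  t <- track$t; x <- track$x; y <- track$y
  keep <- logical(nrow(track))
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:nrow(track)) {
    dt_h <- (t[i] - t[last]) * 24
    sp <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2) / 1000 / dt_h
    if (is.finite(sp) && sp <= max_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  removed <- sum(!keep)
  if (removed / nrow(track) > 0.5)
    stop("speed filter removed >50% of fixes; track unusable")
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("class", "fix_interval", "animal_year", "truth")] <-
    attributes(track)[c("class", "fix_interval", "animal_year", "truth")]
  attr(out, "removed") <- removed
  attr(out, "removed_fraction") <- removed / nrow(track)
  out
}

#' Net squared displacement
#'
#' Squared straight-line displacement of every fix from an origin fix,
#' in km². Its rise and plateau delineate migration timing.
#'
#' @param track a `deer_track`.
#' @param origin row index of the origin fix (default first fix).
#' @return data frame `t`, `nsd` (km²).
#' @export
nsd <- function(track, origin = 1L) {
  stopifnot(origin >= 1, origin <= nrow(track))
  data.frame(t = track$t,
             nsd = ((track$x - track$x[origin])^2 +
                    (track$y - track$y[origin])^2) / 1e6)
}

#' Segment a spring migration from an NSD series
#'
#' Fits a sigmoidal NSD migration model to daily mean NSD by nonlinear
#' least squares and defines the start and end of migration as the days
#' the fitted curve crosses 2.5% and 97.5% of the asymptote
#' \eqn{\delta}. The default model is the Richards generalization of the
#' logistic,
#' \deqn{NSD(t) = \delta\,(1 + e^{(\theta - t)/\phi})^{-\nu},}
#' whose shape parameter \eqn{\nu} absorbs the asymmetry of real NSD
#' curves (displacement squared rises slowly at departure), halving the
#' start-date bias the symmetric logistic (\eqn{\nu = 1}, available as
#' `shape = "logistic"`) shows on simulated migrations. Tracks whose
#' maximum NSD never reaches `min_delta_km2` are classified resident.
#'
#' @param nsd_series data frame from [nsd()].
#' @param track optional `deer_track` matching `nsd_series`; when given,
#'   the arrival date is re-estimated from the time-reversed NSD measured
#'   from the track's final fix (the arrival corner then presents itself
#'   as a departure corner, which the model localizes much better than a
#'   plateau corner), and the straight-line migration distance is
#'   measured between mean positions before the start and after the end.
#' @param min_delta_km2 minimum NSD asymptote for a migration, km²
#'   (default 100 = a 10-km displacement).
#' @param shape `"richards"` (default) or `"logistic"`.
#' @return a `migration_window`: list with `start_date`, `end_date`,
#'   `duration`, `distance_km`, `nsd_fit` (delta, theta, phi, nu), and
#'   `resident` flag (a resident result carries only the flag).
#' @export
segment_migration <- function(nsd_series, track = NULL,
                              min_delta_km2 = 100,
                              shape = c("richards", "logistic")) {
  shape <- match.arg(shape)
  p <- .fit_nsd_model(nsd_series$t, nsd_series$nsd, shape, min_delta_km2)
  if (is.null(p))
    return(structure(list(resident = TRUE), class = "migration_window"))
  cross <- function(p, q) p$theta - p$phi * log(q^(-1 / p$nu) - 1)
  start <- cross(p, 0.025)
  end <- cross(p, 0.975)

  if (!is.null(track)) {
    # arrival from the time-reversed NSD anchored on the final fix
    t0 <- min(track$t) + max(track$t)
    rev_nsd <- ((track$x - track$x[nrow(track)])^2 +
                (track$y - track$y[nrow(track)])^2) / 1e6
    pr <- .fit_nsd_model(t0 - track$t, rev_nsd, shape, min_delta_km2)
    if (!is.null(pr)) {
      end_rev <- t0 - cross(pr, 0.025)
      if (end_rev > start) end <- end_rev
    }
  }

  dist_km <- sqrt(p[["delta"]])
  if (!is.null(track)) {
    pre <- track$t <= start
    post <- track$t >= end
    if (any(pre) && any(post)) {
      dist_km <- sqrt((mean(track$x[post]) - mean(track$x[pre]))^2 +
                      (mean(track$y[post]) - mean(track$y[pre]))^2) / 1000
    }
  }
  structure(list(start_date = start, end_date = end,
                 duration = end - start, distance_km = dist_km,
                 nsd_fit = as.list(p), resident = FALSE),
            class = "migration_window")
}

# Richards/logistic NSD fit on daily means; returns coefficient list
# (delta, theta, phi, nu) or NULL when no migration signal / no fit.
.fit_nsd_model <- function(t, nsd, shape, min_delta_km2) {
  daily <- stats::aggregate(nsd ~ day,
                            data.frame(day = floor(t), nsd = nsd),
                            FUN = mean)
  daily$day <- daily$day + 0.5           # stamp at the day's midpoint
  if (max(daily$nsd) < min_delta_km2) return(NULL)

  delta0 <- max(daily$nsd)
  theta0 <- daily$day[which.min(abs(daily$nsd - delta0 / 2))]
  phi0 <- max(diff(range(daily$day)) / 10, 1)
  lo <- c(min_delta_km2, min(daily$day) - 50, 0.1)
  hi <- c(4 * delta0, max(daily$day) + 50, 400)
  one_fit <- function(nu0) tryCatch(
    if (shape == "richards") {
      minpack.lm::nlsLM(
        nsd ~ delta * (1 + exp((theta - day) / phi))^(-nu), data = daily,
        start = list(delta = delta0, theta = theta0, phi = phi0, nu = nu0),
        lower = c(lo, 0.02), upper = c(hi, 50),
        control = minpack.lm::nls.lm.control(maxiter = 400))
    } else {
      minpack.lm::nlsLM(
        nsd ~ delta / (1 + exp((theta - day) / phi)), data = daily,
        start = list(delta = delta0, theta = theta0, phi = phi0),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 400))
    },
    error = function(e) NULL)
  # the shape parameter has local optima; multi-start and keep best RSS
  fits <- Filter(Negate(is.null),
                 lapply(if (shape == "richards") c(0.5, 1, 3) else 1,
                        one_fit))
  if (length(fits) == 0) return(NULL)
  fit <- fits[[which.min(vapply(fits, function(f)
    sum(stats::residuals(f)^2), numeric(1)))]]
  p <- as.list(stats::coef(fit))
  if (is.null(p$nu)) p$nu <- 1
  p
}

#' @export
print.migration_window <- function(x, ...) {
  if (isTRUE(x$resident)) {
    cat("<migration_window> resident (no migration detected)\n")
  } else {
    cat(sprintf(
      "<migration_window> days %.1f-%.1f (%.1f d), %.1f km straight-line\n",
      x$start_date, x$end_date, x$duration, x$distance_km))
  }
  invisible(x)
}

#' Migration movement rate
#'
#' Straight-line migration distance divided by migration duration.
#'
#' @param window a `migration_window`.
#' @return km/day; 0 with a warning for a zero-displacement loop.
#' @export
movement_rate <- function(window) {
  stopifnot(inherits(window, "migration_window"), !isTRUE(window$resident))
  if (window$duration <= 0) stop("zero-duration migration window")
  if (window$distance_km == 0)
    warning("zero straight-line displacement (loop migration)",
            call. = FALSE)
  window$distance_km / window$duration
}
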