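#' Estimate Brownian bridge motion variance
#'
#' Leave-one-out maximum likelihood: every second fix is treated as an
#' observation of the Brownian bridge spanning its two neighbors. Under
#' the model the interior fix is bivariate normal around the
#' time-interpolated endpoint positions with per-axis variance
#' \deqn{\sigma^2(t) = T\alpha(1-\alpha)\sigma^2_m +
#'   (1-\alpha)^2\delta^2 + \alpha^2\delta^2}
#' where `T` is the bridge duration, `alpha` the fractional time of the
#' interior fix and `delta` the GPS location error. The motion variance
#' \eqn{\sigma^2_m} is found by 1-D likelihood maximization. Time is
#' measured in minutes, so \eqn{\sigma^2_m} is in m²/min (the scale on
#' which motion variances of a few hundred to a few thousand are typical
#' for migrating ungulates).
#'
#' @param track a cleaned `deer_track`.
#' @param location_error GPS error SD, meters.
#' @param max_lag_h bridges spanning longer gaps are excluded.
#' @param interval search interval for \eqn{\sigma^2_m} (m²/min).
#' @return the estimate (numeric), with attributes `loglik`, `n_triples`
#'   and `at_bound` (TRUE when the optimizer ran to an interval edge).
#' @export
estimate_motion_variance <- function(track, location_error = 20,
                                     max_lag_h = 8,
                                     interval = c(1e-3, 1e6)) {
  if (nrow(track) < 3) stop("need at least 3 fixes")
  tm <- track$t * 1440  # minutes
  idx <- seq(2, nrow(track) - 1, by = 2)
  T_all <- tm[idx + 1] - tm[idx - 1]
  ok <- T_all > 0 & T_all <= 2 * max_lag_h * 60
  idx <- idx[ok]
  if (length(idx) == 0) stop("no usable leave-one-out triples")
  Tt <- tm[idx + 1] - tm[idx - 1]
  a <- (tm[idx] - tm[idx - 1]) / Tt
  mx <- (1 - a) * track$x[idx - 1] + a * track$x[idx + 1]
  my <- (1 - a) * track$y[idx - 1] + a * track$y[idx + 1]
  dx <- track$x[idx] - mx
  dy <- track$y[idx] - my

  nll <- function(s2m) {
    v <- Tt * a * (1 - a) * s2m + ((1 - a)^2 + a^2) * location_error^2
    -sum(stats::dnorm(dx, 0, sqrt(v), log = TRUE) +
         stats::dnorm(dy, 0, sqrt(v), log = TRUE))
  }
  opt <- stats::optimize(function(ls) nll(exp(ls)), log(interval))
  est <- exp(opt$minimum)
  at_bound <- min(abs(opt$minimum - log(interval))) < 1e-3
  structure(est, loglik = -opt$objective, n_triples = length(idx),
            at_bound = at_bound)
}

#' Brownian bridge utilization distribution
#'
#' Discretizes the time-weighted average of the Gaussian occupancy along
#' every Brownian bridge between consecutive fixes onto a regular grid
#' and normalizes to total mass 1. Bridges across gaps longer than
#' `max_lag_h` are excluded (long bridges are uninformative and
#' unrealistically diffuse).
#'
#' @param track a cleaned `deer_track`.
#' @param sigma2m motion variance, m²/min (see
#'   [estimate_motion_variance()]).
#' @param cell grid resolution, meters.
#' @param location_error GPS error SD, meters.
#' @param max_lag_h maximum bridged gap, hours.
#' @param n_steps_min integration points per bridge are
#'   `max(5, ceiling(T / n_steps_min))` with `T` in minutes.
#' @return a `bbmm_ud`: list with `ud` (matrix, rows = x, cols = y, sum
#'   1), `xg`, `yg`, `cell`, `motion_variance`.
#' @export
bbmm_ud <- function(track, sigma2m, cell = 150, location_error = 20,
                    max_lag_h = 8, n_steps_min = 15) {
  stopifnot(nrow(track) >= 2, sigma2m > 0)
  tm <- track$t * 1440
  gaps <- diff(tm)
  use <- gaps > 0 & gaps <= max_lag_h * 60
  if (!any(use)) stop("no bridgeable fix pairs within the maximum lag")

  sd_max <- sqrt(max(gaps[use]) / 4 * sigma2m + location_error^2)
  buf <- 4 * sd_max + cell
  xg <- seq(min(track$x) - buf, max(track$x) + buf, by = cell)
  yg <- seq(min(track$y) - buf, max(track$y) + buf, by = cell)
  ud <- matrix(0, length(xg), length(yg))

  for (i in which(use)) {
    Tt <- gaps[i]
    m <- max(5L, ceiling(Tt / n_steps_min))
    al <- (seq_len(m) - 0.5) / m
    sds <- sqrt(Tt * al * (1 - al) * sigma2m +
                ((1 - al)^2 + al^2) * location_error^2)
    mxs <- (1 - al) * track$x[i] + al * track$x[i + 1]
    mys <- (1 - al) * track$y[i] + al * track$y[i + 1]
    w <- Tt / m
    for (j in seq_len(m)) {
      r <- 4 * sds[j] + cell
      ix <- which(xg >= mxs[j] - r & xg <= mxs[j] + r)
      iy <- which(yg >= mys[j] - r & yg <= mys[j] + r)
      # exact Gaussian mass per cell (integral over the cell, not the
      # center density) keeps the discretized bridge faithful at coarse
      # grids
      px <- stats::pnorm(xg[ix] + cell / 2, mxs[j], sds[j]) -
        stats::pnorm(xg[ix] - cell / 2, mxs[j], sds[j])
      py <- stats::pnorm(yg[iy] + cell / 2, mys[j], sds[j]) -
        stats::pnorm(yg[iy] - cell / 2, mys[j], sds[j])
      ud[ix, iy] <- ud[ix, iy] + w * outer(px, py)
    }
  }
  ud <- ud / sum(ud)
  structure(list(ud = ud, xg = xg, yg = yg, cell = cell,
                 motion_variance = sigma2m),
            class = c("bbmm_ud", "ud_grid"))
}

#' Motion-variance quality gate
#'
#' Animal-years with motion variance above the threshold have tracks too
#' diffuse for stopover delineation and are excluded.
#'
#' @param x a `bbmm_ud`, or the motion-variance estimate itself.
#' @param threshold m²/min; the boundary is inclusive (pass at exactly
#'   the threshold).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
variance_gate <- function(x, threshold = 8000) {
  s2 <- if (inherits(x, "bbmm_ud")) x$motion_variance else as.numeric(x)
  s2 <= threshold
}

# Label connected components (8-neighbor) of a logical matrix.
# Returns an integer matrix: 0 = background, 1..k = component ids.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  nr <- nrow(mask)
  nbr <- expand.grid(di = -1:1, dj = -1:1)
  nbr <- nbr[!(nbr$di == 0 & nbr$dj == 0), ]
  for (start in which(mask & lab == 0L)) {
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- (cur - 1) %% nr + 1
      j <- (cur - 1) %/% nr + 1
      ni <- i + nbr$di
      nj <- j + nbr$dj
      okn <- ni >= 1 & ni <= nr & nj >= 1 & nj <= ncol(mask)
      cand <- (nj[okn] - 1) * nr + ni[okn]
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- k
      queue <- c(queue, cand)
    }
  }
  lab
}

#' Delineate high-use stopovers and residence days
#'
#' Takes the 10% highest-density isopleth of the Brownian bridge UD (the
#' smallest region holding 10% of occupancy mass), splits it into
#' 8-neighbor connected components, and credits each component with
#' `fix count x fix interval / 24` days of residence. Components used
#' for fewer than `min_days` days are dropped; an empty set is a valid
#' result (an animal that never lingered).
#'
#' @param track the `deer_track` whose fixes built the UD.
#' @param bbmm a `bbmm_ud`.
#' @param level isopleth mass for high-use areas (default 0.10).
#' @param min_days minimum residence to count as a stopover.
#' @param fix_interval hours between fixes; defaults to the track
#'   attribute.
#' @return a `stopover_set`: list with `stopovers` (data frame:
#'   stopover_id, n_cells, n_fixes, days), `total_days`, `level`.
#' @export
stopover_days <- function(track, bbmm, level = 0.10, min_days = 3,
                          fix_interval = attr(track, "fix_interval")) {
  stopifnot(inherits(bbmm, "bbmm_ud"), !is.null(fix_interval))
  iso <- isopleth(bbmm, level)
  lab <- label_components(iso)
  ix <- pmin(pmax(round((track$x - bbmm$xg[1]) / bbmm$cell) + 1, 1),
             length(bbmm$xg))
  iy <- pmin(pmax(round((track$y - bbmm$yg[1]) / bbmm$cell) + 1, 1),
             length(bbmm$yg))
  fix_lab <- lab[cbind(ix, iy)]
  comps <- seq_len(max(lab))
  if (max(lab) == 0L) {
    st <- data.frame(stopover_id = integer(0), n_cells = integer(0),
                     n_fixes = integer(0), days = numeric(0))
  } else {
    st <- data.frame(
      stopover_id = comps,
      n_cells = vapply(comps, function(k) sum(lab == k), integer(1)),
      n_fixes = vapply(comps, function(k) sum(fix_lab == k), integer(1)))
    st$days <- st$n_fixes * fix_interval / 24
    st <- st[st$days >= min_days, , drop = FALSE]
    rownames(st) <- NULL
  }
  structure(list(stopovers = st, total_days = sum(st$days), level = level),
            class = "stopover_set")
}

#' @export
print.stopover_set <- function(x, ...) {
  cat(sprintf("<stopover_set> %d stopover(s), %.1f total days\n",
              nrow(x$stopovers), x$total_days))
  invisible(x)
}
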