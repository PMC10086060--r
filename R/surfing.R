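#' Days-From-Peak for every fix of a track
#'
#' Signed difference between the date of each GPS fix and the date of
#' peak IRG at the fix's location. The sign convention used throughout
#' the package is `DFP = fix date - local peak date`: positive = behind
#' the wave (after peak), negative = ahead of it; 0 is perfect surfing.
#' Fixes falling on cells without phenology are dropped and counted.
#'
#' @param track a `deer_track` (corridor along +y, meters).
#' @param landscape a `pheno_raster`.
#' @return data frame `t`, `km` (along-corridor position), `dfp` (days),
#'   with attribute `dropped` (fix count without phenology).
#' @export
days_from_peak <- function(track, landscape) {
  km <- track$y / 1000
  pk <- peak_date_at(landscape, km)
  ok <- !is.na(pk)
  out <- data.frame(t = track$t[ok], km = km[ok], dfp = track$t[ok] - pk[ok])
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Aggregate Days-From-Peak per day and kilometer
#'
#' Averages DFP within each (day, 1-km bin) cell of an individual's
#' migration to reduce pseudoreplication from frequent fixes, then
#' summarizes the migration as the mean of the bin means. `dfp_start` and
#' `dfp_end` are the mean DFP over the first and last migration day.
#'
#' @param dfp_records data frame from [days_from_peak()] (optionally
#'   clipped to the migration window first).
#' @param animal_year identifier stored in the profile.
#' @return a `surf_profile`: list with `records` (day, km_bin, mean_dfp,
#'   n_fixes), `mean_dfp`, `dfp_start`, `dfp_end`, `animal_year`.
#' @export
aggregate_dfp <- function(dfp_records, animal_year = NA_character_) {
  if (nrow(dfp_records) == 0) stop("no DFP records to aggregate")
  day <- floor(dfp_records$t)
  km_bin <- floor(dfp_records$km)
  agg <- stats::aggregate(
    dfp_records$dfp, list(day = day, km_bin = km_bin),
    FUN = mean)
  names(agg)[3] <- "mean_dfp"
  cnt <- stats::aggregate(dfp_records$dfp, list(day = day, km_bin = km_bin),
                          FUN = length)
  agg$n_fixes <- cnt$x
  agg <- agg[order(agg$day, agg$km_bin), ]
  rownames(agg) <- NULL
  structure(list(records = agg,
                 mean_dfp = mean(agg$mean_dfp),
                 dfp_start = mean(agg$mean_dfp[agg$day == min(agg$day)]),
                 dfp_end = mean(agg$mean_dfp[agg$day == max(agg$day)]),
                 animal_year = animal_year),
            class = "surf_profile")
}

#' @export
print.surf_profile <- function(x, ...) {
  cat(sprintf(
    "<surf_profile> %s: %d day-km records, mean DFP %+.1f (start %+.1f, end %+.1f)\n",
    x$animal_year, nrow(x$records), x$mean_dfp, x$dfp_start, x$dfp_end))
  invisible(x)
}

#' Phenological mismatch at the start or end of migration
#'
#' Signed difference between a migration date and the mean peak-IRG date
#' of the corresponding seasonal range, under the package-wide sign
#' convention (migration date − mean peak date): negative = ahead of the
#' wave. The start mismatch uses the winter range, the end mismatch the
#' summer range.
#'
#' @param window a `migration_window`.
#' @param range a `seasonal_range` carrying `mean_peak_date`.
#' @return signed mismatch, days.
#' @export
range_mismatch <- function(window, range) {
  stopifnot(inherits(window, "migration_window"), !isTRUE(window$resident),
            inherits(range, "seasonal_range"))
  if (!is.finite(range$mean_peak_date))
    stop("seasonal range has no mean peak date")
  date <- if (range$season == "winter") window$start_date
          else window$end_date
  date - range$mean_peak_date
}

#' Green-wave propagation along the corridor
#'
#' Per-km mean peak-IRG date over all corridor cells within `max_km` of
#' the origin, the sign of its rate of change, and ordinary
#' least-squares regressions of mean peak date on distance within each
#' run of constant sign. Negative segments mark a non-consecutive wave
#' that propagates backwards toward the winter range. The sign is taken
#' on a running-mean smoothed profile (window `smooth_window` km) so
#' cell-level noise does not fragment the segments; the regressions use
#' the raw per-km means.
#'
#' @param landscape a `pheno_raster`.
#' @param max_km corridor extent analyzed, km.
#' @param smooth_window running-mean window (km, odd) for the sign of the
#'   rate of change; 1 = raw differences.
#' @param min_segment_km runs of constant sign shorter than this are
#'   absorbed into their neighbors, so segments describe corridor-scale
#'   wave structure rather than cell-level noise; 0 keeps every run.
#' @return a `wave_profile`: list with `per_km` (km, mean_peak_date),
#'   `segments` (km_start, km_end, direction, slope, p_value, n_bins;
#'   slope/p are `NA` for segments under 3 bins), and `overall`
#'   (full-corridor regression slope and p).
#' @export
wave_propagation <- function(landscape, max_km = 240, smooth_window = 5,
                             min_segment_km = 5) {
  df <- landscape[landscape$km <= max_km, , drop = FALSE]
  km_bin <- floor(df$km)
  per_km <- stats::aggregate(df$peak_date, list(km = km_bin), FUN = mean)
  names(per_km)[2] <- "mean_peak_date"

  # running mean with shrinking windows at the corridor ends
  h <- (smooth_window - 1) %/% 2
  np <- nrow(per_km)
  sm <- vapply(seq_len(np), function(i)
    mean(per_km$mean_peak_date[max(1, i - h):min(np, i + h)]), numeric(1))
  rate <- diff(sm)
  dir <- ifelse(rate >= 0, "positive", "negative")
  # absorb sub-scale runs into their neighbors
  repeat {
    runs <- rle(dir)
    if (length(runs$lengths) <= 1) break
    j <- which.min(runs$lengths)
    if (runs$lengths[j] >= min_segment_km) break
    nb <- if (j == 1) 2 else j - 1
    idx <- (c(0, cumsum(runs$lengths))[j] + 1):cumsum(runs$lengths)[j]
    dir[idx] <- runs$values[nb]
  }
  runs <- rle(dir)
  ends <- cumsum(runs$lengths) + 1   # index into per_km rows
  starts <- c(1, utils::head(ends, -1))

  seg <- do.call(rbind, lapply(seq_along(runs$values), function(i) {
    rows <- starts[i]:ends[i]
    slope <- p <- NA_real_
    if (length(rows) >= 3) {
      fit <- stats::lm(mean_peak_date ~ km, per_km[rows, ])
      co <- suppressWarnings(summary(fit))$coefficients
      slope <- co["km", "Estimate"]
      p <- co["km", "Pr(>|t|)"]
    }
    data.frame(km_start = per_km$km[starts[i]], km_end = per_km$km[ends[i]],
               direction = runs$values[i], slope = slope, p_value = p,
               n_bins = length(rows))
  }))

  ofit <- suppressWarnings(
    summary(stats::lm(mean_peak_date ~ km, per_km)))$coefficients
  structure(list(per_km = per_km, segments = seg,
                 overall = list(slope = ofit["km", "Estimate"],
                                p_value = ofit["km", "Pr(>|t|)"])),
            class = "wave_profile")
}

#' @export
print.wave_profile <- function(x, ...) {
  cat(sprintf("<wave_profile> %d km bins, %d sign segments, overall slope %.3f d/km (p=%.2g)\n",
              nrow(x$per_km), nrow(x$segments), x$overall$slope,
              x$overall$p_value))
  invisible(x)
}

#' Weekly median IRG along the corridor
#'
#' Median IRG per km bin and week, for visualizing the weekly propagation
#' of the green wave. Optionally adds a loess-smoothed display column per
#' week.
#'
#' @param landscape a `pheno_raster`.
#' @param week_starts vector of day-of-year week start days; each week
#'   covers `[start, start + 7)`.
#' @param smooth add a `smoothed` loess column (display only)?
#' @return data frame `week_start`, `km`, `median_irg` (+ `smoothed`).
#' @export
weekly_wave_profile <- function(landscape, week_starts, smooth = FALSE) {
  km_bin <- floor(landscape$km)
  out <- do.call(rbind, lapply(week_starts, function(w0) {
    days <- w0 + 0:6
    med <- vapply(split(seq_len(nrow(landscape)), km_bin), function(rows) {
      vals <- unlist(lapply(rows, function(r) {
        cv <- pheno_curve(landscape$xmidS[r], landscape$scalS[r],
                          landscape$xmidA[r], landscape$scalA[r])
        irg(cv, days)
      }))
      stats::median(vals)
    }, numeric(1))
    data.frame(week_start = w0, km = as.numeric(names(med)),
               median_irg = unname(med))
  }))
  rownames(out) <- NULL
  if (smooth) {
    out$smoothed <- stats::ave(
      out$median_irg, out$week_start,
      FUN = function(v) {
        if (length(v) < 10) return(v)
        stats::fitted(stats::loess(v ~ seq_along(v), span = 0.3))
      })
  }
  out
}

#' Foraging-penalty profile along the corridor
#'
#' Mean loss-in-IRG per corridor quarter, plus the last/first quarter
#' ratio — the machinery behind comparing the cost of mismatch where
#' green-up is slow versus rapid and fleeting.
#'
#' @param landscape a `pheno_raster`.
#' @param max_km corridor extent analyzed, km.
#' @return list with `per_quarter` (quarter, km_start, km_end,
#'   mean_loss_pct, n_cells) and `ratio_last_first`.
#' @export
penalty_profile <- function(landscape, max_km = 240) {
  df <- landscape[landscape$km <= max_km, , drop = FALSE]
  loss <- vapply(seq_len(nrow(df)), function(r) {
    loss_in_irg(pheno_curve(df$xmidS[r], df$scalS[r], df$xmidA[r],
                            df$scalA[r]))
  }, numeric(1))
  brk <- seq(0, max_km, length.out = 5)
  q <- cut(df$km, brk, labels = FALSE, include.lowest = TRUE)
  per <- data.frame(
    quarter = 1:4,
    km_start = brk[1:4], km_end = brk[2:5],
    mean_loss_pct = vapply(1:4, function(i) mean(loss[q == i]), numeric(1)),
    n_cells = vapply(1:4, function(i) sum(q == i), integer(1)))
  list(per_quarter = per,
       ratio_last_first = per$mean_loss_pct[4] / per$mean_loss_pct[1])
}
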