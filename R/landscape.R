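#' Specification of a synthetic green-wave corridor
#'
#' Parameterizes a one-dimensional migration corridor (distance along the
#' route, south to north) on which the date of peak green-up advances with
#' distance — a green wave — except over an initial "no-wave" segment where
#' peak dates are flat or reversed, emulating a desert winter range whose
#' local cues say nothing about conditions up the route. Green-up becomes
#' steeper (smaller spring scale) toward the corridor end, making it more
#' rapid and fleeting near the summer range.
#'
#' @param corridor_length corridor length, km.
#' @param cell_size grid cell size along the corridor, km.
#' @param no_wave_length length of the initial segment without a
#'   consecutive wave, km (0 for a pure wave).
#' @param wave_slope days of peak-date advance per km past the no-wave
#'   segment. The default 0.25 d/km makes the wave sweep the corridor at
#'   4 km/day, bracketed by realistic ungulate migration rates.
#' @param no_wave_slope peak-date slope (days/km) inside the no-wave
#'   segment; must be <= 0 (0 = flat, negative = reversed order).
#' @param base_peak_day day-of-year of peak green-up where the wave
#'   segment begins.
#' @param spring_scale_range `c(min, max)` spring scale `scalS` in days;
#'   when `scale_gradient = TRUE`, `scalS` declines linearly from `max` at
#'   the corridor origin to `min` at the far end.
#' @param scale_gradient apply the distal steepening of green-up?
#' @param noise_sd_peakdate SD (days) of i.i.d. noise added to each cell's
#'   peak date.
#' @param ribbon_width_km width of the thin 2-D ribbon the corridor
#'   occupies (used only to place simulated fixes in the plane).
#' @param seed integer seed for the peak-date noise.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(corridor_length = 240, cell_size = 1,
                           no_wave_length = 32, wave_slope = 0.25,
                           no_wave_slope = -0.4, base_peak_day = 110,
                           spring_scale_range = c(4, 12),
                           scale_gradient = TRUE,
                           noise_sd_peakdate = 2, ribbon_width_km = 2,
                           seed = 1L) {
  stopifnot(corridor_length > no_wave_length, no_wave_length >= 0,
            cell_size > 0, all(spring_scale_range > 0),
            length(spring_scale_range) == 2,
            spring_scale_range[1] <= spring_scale_range[2],
            no_wave_slope <= 0, wave_slope >= 0,
            noise_sd_peakdate >= 0, ribbon_width_km > 0)
  structure(list(corridor_length = corridor_length, cell_size = cell_size,
                 no_wave_length = no_wave_length, wave_slope = wave_slope,
                 no_wave_slope = no_wave_slope,
                 base_peak_day = base_peak_day,
                 spring_scale_range = spring_scale_range,
                 scale_gradient = scale_gradient,
                 noise_sd_peakdate = noise_sd_peakdate,
                 ribbon_width_km = ribbon_width_km,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate a gridded phenology landscape
#'
#' Lays out per-cell double-logistic green-up parameters along the
#' corridor. Within the wave segment the expected peak date is
#' `base_peak_day + wave_slope * (km - no_wave_length)`; within the
#' no-wave segment it is constant or decreasing with distance. The peak
#' date of each cell is its spring inflection `xmidS`.
#'
#' @param spec a [landscape_spec()].
#' @return a `pheno_raster`: data frame with one row per cell and columns
#'   `km` (cell center), `xmidS`, `scalS`, `xmidA`, `scalA`, `peak_date`,
#'   plus the spec stored as an attribute.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  km <- seq(spec$cell_size / 2, spec$corridor_length, by = spec$cell_size)
  mu <- ifelse(km < spec$no_wave_length,
               spec$base_peak_day + spec$no_wave_slope *
                 (km - spec$no_wave_length),
               spec$base_peak_day + spec$wave_slope *
                 (km - spec$no_wave_length))
  old <- .Random.seed_save()
  set.seed(spec$seed)
  peak <- mu + stats::rnorm(length(km), 0, spec$noise_sd_peakdate)
  .Random.seed_restore(old)
  sc <- spec$spring_scale_range
  scalS <- if (spec$scale_gradient) {
    sc[2] + (sc[1] - sc[2]) * km / spec$corridor_length
  } else rep(mean(sc), length(km))
  out <- data.frame(km = km, xmidS = peak, scalS = scalS,
                    xmidA = peak + 100, scalA = 12, peak_date = peak)
  structure(out, class = c("pheno_raster", "data.frame"), spec = spec)
}

# Save/restore the global RNG state so seeded generators do not clobber
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Look up landscape cells by corridor distance
#'
#' @param landscape a `pheno_raster`.
#' @param km corridor distance(s), km; positions within one cell of the
#'   corridor ends snap to the boundary cells (seasonal ranges straddle
#'   the ends), anything further out returns `NA`.
#' @return integer row indices into `landscape`.
#' @export
cell_at_km <- function(landscape, km) {
  spec <- attr(landscape, "spec")
  idx <- floor(km / spec$cell_size) + 1L
  idx[km < -spec$cell_size |
        km > spec$corridor_length + spec$cell_size] <- NA_integer_
  pmin(pmax(idx, 1L), nrow(landscape))
}

#' Peak green-up date at corridor positions
#'
#' @inheritParams cell_at_km
#' @return peak-IRG day-of-year per position (`NA` off the corridor).
#' @export
peak_date_at <- function(landscape, km) {
  landscape$peak_date[cell_at_km(landscape, km)]
}

#' @export
print.pheno_raster <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "<pheno_raster> %d cells, %.0f km corridor (%.0f km no-wave), peak %.0f-%.0f\n",
    nrow(x), spec$corridor_length, spec$no_wave_length,
    min(x$peak_date), max(x$peak_date)))
  invisible(x)
}

#' Write / read a phenology landscape as gridded CSV
#'
#' Plain-text interchange format: one row per cell, columns `km`, `xmidS`,
#' `scalS`, `xmidA`, `scalA`, `peak_date`; grid geometry is stored in
#' `# key: value` header comments.
#'
#' @param landscape a `pheno_raster`.
#' @param path file path.
#' @return `path` (write) or the `pheno_raster` (read).
#' @export
write_landscape_csv <- function(landscape, path) {
  spec <- attr(landscape, "spec")
  hdr <- sprintf("# %s: %s", c("corridor_length_km", "cell_size_km",
                               "no_wave_length_km", "ribbon_width_km"),
                 c(spec$corridor_length, spec$cell_size,
                   spec$no_wave_length, spec$ribbon_width_km))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(landscape), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), ": "))
  geom <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.csv(path, comment.char = "#")
  spec <- landscape_spec(
    corridor_length = geom[["corridor_length_km"]],
    cell_size = geom[["cell_size_km"]],
    no_wave_length = geom[["no_wave_length_km"]],
    ribbon_width_km = geom[["ribbon_width_km"]],
    noise_sd_peakdate = 0)
  structure(df, class = c("pheno_raster", "data.frame"), spec = spec)
}
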