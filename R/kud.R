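#' Kernel utilization distribution on a regular grid
#'
#' Product bivariate Gaussian kernel density, normalized to sum to 1 over
#' the grid. The default bandwidth is the per-axis reference bandwidth
#' \eqn{h_i = \sigma_i n^{-1/6}}, the movement-ecology default for home
#' range estimation.
#'
#' @param x,y point coordinates, meters.
#' @param bandwidth length-2 bandwidth `c(hx, hy)` in meters, or `NULL`
#'   for the reference bandwidth.
#' @param cell grid cell size, meters.
#' @param expand grid margin beyond the point extent, in bandwidths.
#' @return a `ud_grid`: list with `ud` (matrix, rows = x, cols = y,
#'   summing to 1), `xg`, `yg` (cell-center coordinates), `cell`,
#'   `bandwidth`.
#' @export
kernel_ud <- function(x, y, bandwidth = NULL, cell = 150, expand = 4) {
  stopifnot(length(x) == length(y), length(x) >= 1, cell > 0)
  n <- length(x)
  if (is.null(bandwidth)) {
    h <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
    # degenerate axis (identical coordinates): point mass in one cell
    h[!is.finite(h) | h <= 0] <- cell / 100
    bandwidth <- h
  }
  stopifnot(length(bandwidth) == 2, all(bandwidth > 0))
  xg <- seq(min(x) - expand * bandwidth[1], max(x) + expand * bandwidth[1],
            by = cell)
  yg <- seq(min(y) - expand * bandwidth[2], max(y) + expand * bandwidth[2],
            by = cell)
  # product kernel: sum_i dnorm(xg - x_i) dnorm(yg - y_i) via crossprod
  Kx <- outer(x, xg, function(p, g) stats::dnorm(g, p, bandwidth[1]))
  Ky <- outer(y, yg, function(p, g) stats::dnorm(g, p, bandwidth[2]))
  ud <- crossprod(Kx, Ky)
  ud <- ud / sum(ud)
  structure(list(ud = ud, xg = xg, yg = yg, cell = cell,
                 bandwidth = bandwidth),
            class = "ud_grid")
}

#' Highest-density isopleth of a utilization distribution
#'
#' The smallest set of highest-density cells whose cumulative mass
#' reaches the requested fraction.
#'
#' @param ud a `ud_grid` (from [kernel_ud()]) or `bbmm_ud` object.
#' @param mass fraction of UD mass in `(0, 1]`.
#' @return logical matrix (same shape as the UD) marking isopleth cells,
#'   with attributes `area_km2` and `mass_captured`.
#' @export
isopleth <- function(ud, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  m <- ud$ud
  if (mass == 1) {
    sel <- which(m > 0)
  } else {
    ord <- order(m, decreasing = TRUE)
    cs <- cumsum(m[ord])
    k <- which(cs >= mass - 1e-12)[1]
    sel <- ord[seq_len(k)]
    sel <- sel[m[sel] > 0]
  }
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[sel] <- TRUE
  attr(out, "area_km2") <- length(sel) * (ud$cell / 1000)^2
  attr(out, "mass_captured") <- sum(m[sel])
  out
}

#' Delineate a seasonal range and its mean peak green-up date
#'
#' Builds the 95% kernel UD isopleth from the fixes a deer used on a
#' seasonal range (winter: between arrival from autumn migration — or
#' first fix — and the start of spring migration; summer: after the end
#' of spring migration) and averages the landscape peak-IRG date over the
#' isopleth cells.
#'
#' @param track a cleaned `deer_track`.
#' @param window a `migration_window` for the spring migration.
#' @param landscape a `pheno_raster`.
#' @param season `"winter"` or `"summer"`.
#' @param level isopleth mass (default 0.95).
#' @param cell KUD grid cell size, meters.
#' @return a `seasonal_range`: list with `season`, `area_km2`,
#'   `mean_peak_date`, `n_fixes`.
#' @export
seasonal_range <- function(track, window, landscape,
                           season = c("winter", "summer"),
                           level = 0.95, cell = 150) {
  season <- match.arg(season)
  stopifnot(!isTRUE(window$resident))
  keep <- if (season == "winter") track$t <= window$start_date
          else track$t >= window$end_date
  pts <- track[keep, , drop = FALSE]
  if (nrow(pts) < 10)
    stop("fewer than 10 fixes on the ", season, " range")
  ud <- kernel_ud(pts$x, pts$y, cell = cell)
  iso <- isopleth(ud, level)
  cells <- which(iso, arr.ind = TRUE)
  km <- ud$yg[cells[, 2]] / 1000
  pk <- peak_date_at(landscape, km)
  if (all(is.na(pk)))
    stop("seasonal range does not overlap the phenology landscape")
  structure(list(season = season,
                 area_km2 = attr(iso, "area_km2"),
                 mean_peak_date = mean(pk, na.rm = TRUE),
                 n_fixes = nrow(pts)),
            class = "seasonal_range")
}
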