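# Shared fixture builders (all generated in code; no stored data).

# small noiseless wave landscape for fast tests
tiny_landscape <- function(corridor_length = 60, no_wave_length = 0,
                           wave_slope = 0.25, noise = 0, seed = 1,
                           ...) {
  make_landscape(landscape_spec(
    corridor_length = corridor_length, no_wave_length = no_wave_length,
    wave_slope = wave_slope, noise_sd_peakdate = noise, seed = seed, ...))
}

# bare track constructor for hand-built fixtures
make_track <- function(t, x, y, fix_interval = 2, id = "t1") {
  structure(data.frame(animal_id = id, t = t, x = x, y = y),
            class = c("deer_track", "data.frame"),
            fix_interval = fix_interval, animal_year = id)
}

# observed Brownian-motion track: interior fixes are true Brownian
# bridges between their neighbours (sigma2m in m^2/min, dt in minutes)
sim_bb_track <- function(sigma2m, n = 60, dt_min = 120, error = 20) {
  step_sd <- sqrt(sigma2m * dt_min)
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
  y <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
  make_track(t = (0:(n - 1)) * dt_min / 1440,
             x = x + stats::rnorm(n, 0, error),
             y = y + stats::rnorm(n, 0, error))
}

# proportional-odds data generator (outcome levels in compensation order)
sim_po_data <- function(n, beta = 0.19, zeta = c(-1, 0.5, 2), xmax = 40) {
  x <- stats::runif(n, 0, xmax)
  cum <- vapply(zeta, function(z) stats::plogis(z - beta * x),
                numeric(n))
  y <- 1 + rowSums(stats::runif(n) > cum)
  lev <- c("non", "perfect", "partial", "full")
  list(x = x, y = factor(lev[y], levels = lev, ordered = TRUE))
}

# independent compensation rule table: evaluates the four verbal rules
# separately and resolves overlaps by the documented precedence
oracle_comp_class <- function(s, e, w = 7) {
  as <- abs(s); ae <- abs(e)
  rules <- c(perfect = as <= w && ae <= w,
             full    = as > w && ae < as,
             partial = as > w && abs(ae - as) <= w,
             non     = ae > as || (as <= w && ae > w))
  stopifnot(any(rules))  # coverage: some rule must fire
  names(rules)[which(rules)[1]]
}
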