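test_that("a fix arriving faster than 10.8 km/h is removed", {
  # two fixes 11 km apart, 1 h apart -> 11 km/h -> second dropped
  tr <- make_track(t = c(0, 1 / 24), x = c(0, 11000), y = c(0, 0))
  out <- speed_filter(tr)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "removed"), 1)
})

test_that("compliant tracks pass the speed filter unchanged", {
  tr <- make_track(t = (0:20) / 12, x = rep(0, 21),
                   y = cumsum(c(0, rep(800, 20))))  # 0.4 km/h
  out <- speed_filter(tr)
  expect_equal(nrow(out), 21)
  expect_equal(out$y, tr$y)
})

test_that("planted teleports are removed exactly and cleaning is idempotent", {
  set.seed(7)
  n <- 100
  t <- (0:(n - 1)) * 2 / 24
  y <- cumsum(c(0, rep(300, n - 1)))     # 0.15 km/h baseline
  x <- rnorm(n, 0, 10)
  bad <- seq(10, n, by = 10)             # every 10th fix teleports 30 km
  x[bad] <- x[bad] + 30000
  tr <- make_track(t, x, y)
  out <- speed_filter(tr)
  expect_equal(attr(out, "removed"), length(bad))
  expect_false(any(out$x > 15000))
  # re-scan oracle: no remaining consecutive-fix violation
  sp <- sqrt(diff(out$x)^2 + diff(out$y)^2) / 1000 / (diff(out$t) * 24)
  expect_true(all(sp <= 10.8))
  # idempotent
  again <- speed_filter(out)
  expect_equal(attr(again, "removed"), 0)
  expect_equal(again$x, out$x)
})

test_that("a track that is mostly teleports is rejected", {
  t <- (0:9) / 24
  x <- c(0, rep(2e5, 6), rep(0, 3))      # 6 of 10 fixes teleport 200 km
  tr <- make_track(t, x, rep(0, 10))
  expect_error(speed_filter(tr), ">50%")
})

test_that("NSD is squared straight-line displacement in km²", {
  tr <- make_track(t = 0:2, x = c(0, 3000, 500), y = c(0, 4000, 500))
  out <- nsd(tr)
  expect_equal(out$nsd[1], 0)
  expect_equal(out$nsd[2], 25)           # 3-4-5 triangle
  # random-track oracle
  set.seed(12)
  tr2 <- make_track(t = 0:49, x = rnorm(50, 0, 5000), y = rnorm(50, 0, 5000))
  expect_equal(nsd(tr2)$nsd,
               ((tr2$x - tr2$x[1])^2 + (tr2$y - tr2$y[1])^2) / 1e6)
})

test_that("segmentation recovers a known noiseless departure", {
  ls <- make_landscape(landscape_spec(seed = 2))
  ag <- agent_spec(departure_offset = -20, gps_noise_sd = 0,
                   site_wander_sd = 0, seed = 7)
  tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 200))
  w <- segment_migration(nsd(tr))
  expect_lte(abs(w$start_date - attr(tr, "truth")$first_move_day), 2)
  expect_gt(w$duration, 0)
})

test_that("stationary tracks are classified resident", {
  set.seed(3)
  tr <- make_track(t = (0:199) / 12, x = rnorm(200, 0, 100),
                   y = rnorm(200, 0, 100))
  w <- segment_migration(nsd(tr))
  expect_true(w$resident)
})

test_that("segmentation is invariant to time translation and rotation", {
  ls <- tiny_landscape(corridor_length = 240)
  tr <- suppressWarnings(simulate_deer(ls, agent_spec(seed = 9),
                                       n_days = 120))
  w0 <- segment_migration(nsd(tr))
  # time translation
  tr_t <- tr; tr_t$t <- tr$t + 500
  w_t <- segment_migration(nsd(tr_t))
  expect_equal(w_t$start_date - 500, w0$start_date, tolerance = 1e-6)
  # rigid rotation by 35 degrees
  th <- 35 * pi / 180
  tr_r <- tr
  tr_r$x <- cos(th) * tr$x - sin(th) * tr$y
  tr_r$y <- sin(th) * tr$x + cos(th) * tr$y
  w_r <- segment_migration(nsd(tr_r))
  expect_equal(w_r$start_date, w0$start_date, tolerance = 1e-6)
})

test_that("mean absolute start-date recovery error is within 2 days", {
  # constant-speed migrants with jittered departures and speeds
  ls <- make_landscape(landscape_spec(seed = 2))
  set.seed(11)
  n <- 60
  offs <- runif(n, -50, 50)
  spd <- runif(n, 3, 8)
  errs <- vapply(seq_len(n), function(i) {
    ag <- agent_spec(departure_offset = offs[i], base_speed = spd[i],
                     mismatch_gain = 0, stopover_ahead_days = NA,
                     seed = 2000 + i)
    tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 200))
    w <- segment_migration(nsd(tr))
    w$start_date - attr(tr, "truth")$departure_day
  }, numeric(1))
  expect_lte(mean(abs(errs)), 2)
})

test_that("movement rate divides distance by duration", {
  w <- structure(list(start_date = 100, end_date = 150, duration = 50,
                      distance_km = 100, resident = FALSE),
                 class = "migration_window")
  expect_equal(movement_rate(w), 2)
  w0 <- w; w0$distance_km <- 0
  expect_warning(r <- movement_rate(w0), "loop")
  expect_equal(r, 0)
  wz <- w; wz$duration <- 0
  expect_error(movement_rate(wz), "duration")
})

test_that("recovered rate matches a constant-speed agent within 5%", {
  ls <- tiny_landscape(corridor_length = 240, wave_slope = 0)
  ag <- agent_spec(departure_offset = 0, base_speed = 4, mismatch_gain = 0,
                   stopover_ahead_days = NA, seed = 13)
  tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 90))
  w <- segment_migration(nsd(tr), track = tr)
  expect_lt(abs(movement_rate(w) - 4) / 4, 0.05)
})

test_that("kernel UD normalizes and its isopleths behave", {
  set.seed(5)
  x <- rnorm(300, 0, 200); y <- rnorm(300, 0, 300)
  ud <- kernel_ud(x, y, cell = 50)
  expect_lt(abs(sum(ud$ud) - 1), 1e-6)
  iso95 <- isopleth(ud, 0.95)
  expect_gte(attr(iso95, "mass_captured"), 0.95)
  # full-mass isopleth covers every nonzero cell
  iso1 <- isopleth(ud, 1)
  expect_equal(sum(iso1), sum(ud$ud > 0))
  # nesting
  iso50 <- isopleth(ud, 0.5)
  expect_true(all(iso95[iso50]))
})

test_that("identical points give a single-cell UD", {
  ud <- kernel_ud(rep(10, 20), rep(20, 20), cell = 150)
  expect_equal(sum(ud$ud > 1e-12), 1)
})

test_that("95% isopleth area approaches the bivariate-normal ellipse area", {
  set.seed(8)
  sigma <- 100
  x <- rnorm(10000, 0, sigma); y <- rnorm(10000, 0, sigma)
  ud <- kernel_ud(x, y, cell = 10)
  area_m2 <- attr(isopleth(ud, 0.95), "area_km2") * 1e6
  analytic <- qchisq(0.95, 2) * pi * sigma^2
  expect_lt(abs(area_m2 - analytic) / analytic, 0.1)
})

test_that("seasonal ranges carry mean peak dates from the landscape", {
  ls <- make_landscape(landscape_spec(seed = 2))
  tr <- suppressWarnings(simulate_deer(ls, agent_spec(seed = 5),
                                       n_days = 200))
  cl <- speed_filter(tr)
  w <- segment_migration(nsd(cl), track = cl)
  wr <- seasonal_range(cl, w, ls, "winter")
  sr <- seasonal_range(cl, w, ls, "summer")
  # winter range sits at the corridor origin, summer at its end
  expect_lt(abs(wr$mean_peak_date - ls$peak_date[1]), 3)
  expect_lt(abs(sr$mean_peak_date - ls$peak_date[nrow(ls)]), 3)
  expect_gt(wr$area_km2, 0)
})
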