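test_that("noiseless wave landscape has the generating slope everywhere", {
  ls <- tiny_landscape(corridor_length = 100, wave_slope = 0.5)
  d <- diff(ls$peak_date) / diff(ls$km)
  expect_equal(d, rep(0.5, length(d)))
  expect_true(all(diff(ls$peak_date) > 0))  # strictly increasing
})

test_that("reversed no-wave segment regresses with non-positive slope", {
  ls <- make_landscape(landscape_spec(no_wave_length = 32,
                                      no_wave_slope = -0.4,
                                      noise_sd_peakdate = 1, seed = 9))
  first <- ls[ls$km < 32, ]
  slope <- coef(lm(peak_date ~ km, first))[["km"]]
  expect_lte(slope, 0)
})

test_that("landscape generation is deterministic under a fixed seed", {
  spec <- landscape_spec(noise_sd_peakdate = 3, seed = 77)
  expect_identical(make_landscape(spec), make_landscape(spec))
})

test_that("landscape spec rejects invalid geometry", {
  expect_error(landscape_spec(corridor_length = 10, no_wave_length = 20))
  expect_error(landscape_spec(cell_size = 0))
  expect_error(landscape_spec(spring_scale_range = c(-1, 5)))
})

test_that("mismatch-blind agent moves at constant speed", {
  ls <- tiny_landscape(corridor_length = 200)
  ag <- agent_spec(departure_offset = 0, base_speed = 5, mismatch_gain = 0,
                   stopover_ahead_days = NA, gps_noise_sd = 0,
                   site_wander_sd = 0, seed = 3)
  tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 20, pre_days = 0))
  tru <- attr(tr, "truth")
  # continuous constant-speed motion: displacement = speed * elapsed time
  expect_equal(max(tr$y) / 1000, 5 * (max(tr$t) - tru$departure_day),
               tolerance = 1e-8)
  expect_true(isTRUE(tru$truncated))     # 200-km corridor not finished
})

test_that("noise-free fix speeds never exceed max_speed/24 km/h", {
  ls <- tiny_landscape(corridor_length = 240)
  ag <- agent_spec(departure_offset = 10, base_speed = 6, max_speed = 12,
                   gps_noise_sd = 0, site_wander_sd = 0, fix_interval = 2,
                   seed = 5)
  tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 80))
  v_kmh <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / 1000 / (diff(tr$t) * 24)
  expect_true(all(v_kmh <= 12 / 24 + 1e-9))
})

test_that("fixes are strictly time-ordered at the stated interval", {
  ls <- tiny_landscape()
  for (fi in c(1, 2, 3)) {
    tr <- suppressWarnings(simulate_deer(
      ls, agent_spec(fix_interval = fi, seed = 2), n_days = 10,
      pre_days = 2))
    expect_true(all(diff(tr$t) > 0))
    expect_equal(unique(round(diff(tr$t) * 24, 6)), fi)
  }
  expect_error(agent_spec(fix_interval = 4))
})

test_that("agent released behind the wave outpaces one released ahead", {
  ls <- make_landscape(landscape_spec(seed = 2))
  mean_speed <- function(off) {
    tr <- suppressWarnings(simulate_deer(
      ls, agent_spec(departure_offset = off, seed = 8), n_days = 200))
    tru <- attr(tr, "truth")
    (max(tr$y) - min(tr$y)) / 1000 / (tru$arrival_day - tru$first_move_day)
  }
  expect_gt(mean_speed(+25), mean_speed(-25))
})

test_that("an early-departing compensator ends closer to the wave than it started", {
  # run the surfing + classification modules on the simulated track
  ls <- make_landscape(landscape_spec(seed = 2))
  ag <- agent_spec(departure_offset = -30, seed = 4)
  tr <- suppressWarnings(simulate_deer(ls, ag, n_days = 200))
  cl <- speed_filter(tr)
  w <- segment_migration(nsd(cl), track = cl)
  wr <- seasonal_range(cl, w, ls, "winter")
  sr <- seasonal_range(cl, w, ls, "summer")
  s <- range_mismatch(w, wr)
  e <- range_mismatch(w, sr)
  expect_lt(abs(e), abs(s))
  expect_equal(as.character(classify_compensation(s, e)), "full")
})

test_that("cohorts are reproducible and partition into timing classes", {
  ls <- tiny_landscape(corridor_length = 240)
  co1 <- make_cohort(ls, n_animals = 12, seed = 21)
  co2 <- make_cohort(ls, n_animals = 12, seed = 21)
  expect_identical(co1$covariates, co2$covariates)
  expect_identical(co1$tracks, co2$tracks)
  expect_true(all(co1$covariates$age %in% 1:13))
  # timing classifier partitions a uniform-departure cohort non-trivially
  co <- make_cohort(ls, n_animals = 152, departure_span = 100, seed = 3)
  cls <- classify_timing(standardize_start(co$covariates$departure_offset))
  expect_true(all(table(cls) > 0))
  expect_equal(sum(table(cls)), 152)
  expect_error(make_cohort(ls, n_animals = 3))
})

test_that("deterministic timing classes for a four-animal cohort", {
  cls <- classify_timing(standardize_start(c(-30, -10, 10, 30)))
  expect_equal(as.character(cls), c("early", "mid", "mid", "late"))
})

test_that("Movebank CSV round-trips tracks", {
  ls <- tiny_landscape()
  tr <- suppressWarnings(simulate_deer(ls, agent_spec(seed = 6),
                                       n_days = 8, pre_days = 2,
                                       animal_id = "d01"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  expect_match(readLines(path, n = 1), "fix-interval-hours: 2")
  back <- read_tracks_csv(path)[["d01"]]
  expect_equal(back$t, tr$t, tolerance = 1e-4)
  expect_equal(back$x, tr$x, tolerance = 0.01)
  expect_equal(attr(back, "fix_interval"), 2)
})

test_that("landscape CSV round-trips the phenology grid", {
  ls <- make_landscape(landscape_spec(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(ls, path)
  back <- read_landscape_csv(path)
  expect_equal(back$peak_date, ls$peak_date)
  expect_equal(attr(back, "spec")$corridor_length,
               attr(ls, "spec")$corridor_length)
})
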