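test_that("Days-From-Peak follows the sign convention", {
  ls <- tiny_landscape(corridor_length = 50, wave_slope = 0.5,
                       base_peak_day = 100)
  # fix on its cell's peak date -> 0; 5 days after -> +5
  pk <- peak_date_at(ls, 10.5)
  tr <- make_track(t = c(pk, pk + 5), x = c(0, 0), y = c(10500, 10500))
  out <- days_from_peak(tr, ls)
  expect_equal(out$dfp, c(0, 5))
  expect_equal(attr(out, "dropped"), 0)
})

test_that("per-fix DFP equals a cell-by-cell hand lookup and fixes off the raster are counted", {
  ls <- tiny_landscape(corridor_length = 50, noise = 2, seed = 31)
  set.seed(14)
  n <- 120
  tr <- make_track(t = 100 + cumsum(runif(n, 0.05, 0.2)),
                   x = rnorm(n), y = runif(n, -5000, 55000))
  out <- days_from_peak(tr, ls)
  spec <- attr(ls, "spec")
  inside <- tr$y / 1000 >= -spec$cell_size &
    tr$y / 1000 <= spec$corridor_length + spec$cell_size
  expect_equal(nrow(out), sum(inside))
  expect_equal(attr(out, "dropped"), sum(!inside))
  hand <- vapply(which(inside), function(i) {
    cell <- min(max(floor(tr$y[i] / 1000 / spec$cell_size) + 1, 1), nrow(ls))
    tr$t[i] - ls$peak_date[cell]
  }, numeric(1))
  expect_equal(out$dfp, hand)
})

test_that("shifting all fix dates by k shifts every DFP by k", {
  ls <- tiny_landscape(corridor_length = 50, noise = 1, seed = 4)
  set.seed(9)
  tr <- make_track(t = 100 + (1:50) / 5, x = rnorm(50),
                   y = runif(50, 0, 49000))
  base <- days_from_peak(tr, ls)
  tr_k <- tr; tr_k$t <- tr$t + 11
  expect_equal(days_from_peak(tr_k, ls)$dfp, base$dfp + 11)
})

test_that("DFP aggregation means within day-km bins", {
  # 12 fixes in one day and km bin with DFP -2..9 -> one record, mean 3.5
  rec <- data.frame(t = 100 + (0:11) / 12, km = rep(3.4, 12), dfp = -2:9)
  prof <- aggregate_dfp(rec, "a")
  expect_equal(nrow(prof$records), 1)
  expect_equal(prof$records$mean_dfp, 3.5)
  expect_equal(prof$mean_dfp, 3.5)
  expect_error(aggregate_dfp(rec[0, ]), "no DFP")
})

test_that("one-fix-per-bin aggregation is the identity and matches group-by", {
  ls <- tiny_landscape(corridor_length = 30)
  set.seed(6)
  tr <- make_track(t = 100 + 0:29, x = rnorm(30), y = (0:29) * 1000 + 500)
  rec <- days_from_peak(tr, ls)
  prof <- aggregate_dfp(rec)
  expect_equal(nrow(prof$records), 30)
  expect_equal(prof$records$mean_dfp, rec$dfp)
  # random multi-fix track against an independent group-by oracle
  tr2 <- make_track(t = 100 + cumsum(runif(200, 0.02, 0.3)),
                    x = rnorm(200), y = runif(200, 0, 29000))
  rec2 <- days_from_peak(tr2, ls)
  prof2 <- aggregate_dfp(rec2)
  oracle <- tapply(rec2$dfp,
                   interaction(floor(rec2$t), floor(rec2$km), drop = TRUE),
                   mean)
  expect_equal(sort(prof2$records$mean_dfp), sort(as.numeric(oracle)))
  expect_equal(prof2$mean_dfp, mean(prof2$records$mean_dfp))
})

test_that("a perfect surfer has zero mean DFP", {
  ls <- tiny_landscape(corridor_length = 40, wave_slope = 1,
                       base_peak_day = 100)
  # visit each cell exactly on its peak date
  tr <- make_track(t = ls$peak_date, x = rep(0, nrow(ls)),
                   y = ls$km * 1000)
  prof <- aggregate_dfp(days_from_peak(tr, ls))
  expect_equal(prof$mean_dfp, 0)
  expect_equal(as.character(classify_compensation(prof$dfp_start,
                                                  prof$dfp_end)),
               "perfect")
})

test_that("range mismatch is the migration date minus the range peak", {
  w <- structure(list(start_date = 70, end_date = 140, duration = 70,
                      distance_km = 200, resident = FALSE),
                 class = "migration_window")
  wr <- structure(list(season = "winter", mean_peak_date = 100,
                       area_km2 = 1, n_fixes = 50),
                  class = "seasonal_range")
  sr <- structure(list(season = "summer", mean_peak_date = 140,
                       area_km2 = 1, n_fixes = 50),
                  class = "seasonal_range")
  expect_equal(range_mismatch(w, wr), -30)  # 30 days ahead
  expect_equal(range_mismatch(w, sr), 0)
})

test_that("wave propagation recovers a constructed slope exactly", {
  ls <- tiny_landscape(corridor_length = 120, wave_slope = 0.2,
                       base_peak_day = 100)
  wp <- wave_propagation(ls, max_km = 120)
  expect_equal(nrow(wp$segments), 1)
  expect_equal(wp$segments$direction, "positive")
  expect_equal(wp$segments$slope, 0.2, tolerance = 1e-6)
  expect_lt(wp$segments$p_value, 1e-10)
})

test_that("flat noisy landscapes show no significant wave", {
  ls <- make_landscape(landscape_spec(corridor_length = 240,
                                      no_wave_length = 0, wave_slope = 0,
                                      noise_sd_peakdate = 4, seed = 19))
  wp <- wave_propagation(ls)
  expect_gt(wp$overall$p_value, 0.05)
  expect_lt(abs(wp$overall$slope), 0.05)
})

test_that("a reversed initial segment is detected as negative", {
  ls <- make_landscape(landscape_spec(no_wave_length = 32,
                                      no_wave_slope = -0.4,
                                      noise_sd_peakdate = 1, seed = 3))
  wp <- wave_propagation(ls)
  expect_equal(wp$segments$direction[1], "negative")
  expect_lt(wp$segments$km_start[1], 32)
})

test_that("weekly median IRG profiles match per-cell evaluation", {
  ls <- tiny_landscape(corridor_length = 12, wave_slope = 1,
                       base_peak_day = 100, cell_size = 1)
  prof <- weekly_wave_profile(ls, week_starts = c(98, 105))
  # single-cell km bins: median = that cell's IRG median over the week
  for (r in seq_len(nrow(prof))) {
    row <- prof[r, ]
    cell <- which(floor(ls$km) == row$km)
    cv <- pheno_curve(ls$xmidS[cell], ls$scalS[cell], ls$xmidA[cell],
                      ls$scalA[cell])
    expect_equal(row$median_irg, median(irg(cv, row$week_start + 0:6)))
  }
  # a week centered on a cell's peak attains that cell's weekly maximum
  cell <- 6
  pk <- ls$peak_date[cell]
  wk <- weekly_wave_profile(ls, week_starts = c(pk - 17, pk - 3, pk + 11))
  at_cell <- wk[wk$km == floor(ls$km[cell]), ]
  expect_equal(which.max(at_cell$median_irg), 2)
})

test_that("penalty profile is flat for uniform scalS and rises when green-up steepens", {
  flat <- tiny_landscape(corridor_length = 80, scale_gradient = FALSE,
                         spring_scale_range = c(8, 8))
  pp <- penalty_profile(flat, max_km = 80)
  expect_equal(pp$ratio_last_first, 1, tolerance = 1e-9)
  expect_equal(diff(range(pp$per_quarter$mean_loss_pct)), 0,
               tolerance = 1e-9)
  steep <- tiny_landscape(corridor_length = 80,
                          spring_scale_range = c(3, 12))
  ps <- penalty_profile(steep, max_km = 80)
  expect_gt(ps$ratio_last_first, 1)
  expect_gt(ps$per_quarter$mean_loss_pct[4], ps$per_quarter$mean_loss_pct[1])
  # direct averaging oracle
  loss <- vapply(seq_len(nrow(steep)), function(r)
    loss_in_irg(pheno_curve(steep$xmidS[r], steep$scalS[r])), numeric(1))
  expect_equal(ps$per_quarter$mean_loss_pct[1], mean(loss[steep$km <= 20]))
})
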