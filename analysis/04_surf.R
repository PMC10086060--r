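#!/usr/bin/env Rscript
# Stage 4: green-wave surfing metrics.
#
# Computes per-fix Days-From-Peak, aggregates per day and kilometer of
# each migration, measures start/end mismatches against the 95% KUD
# seasonal ranges, and characterizes how the green wave propagates along
# the corridor.

suppressPackageStartupMessages(library(greensurf))

cfg <- read_config_yaml("results/config.yaml")
landscape <- read_landscape_csv("results/landscape.csv")
tracks <- read_tracks_csv("results/tracks.csv")
windows <- read.csv("results/migration_windows.csv")

profiles <- list(); mism <- list()
for (id in windows$animal_year[!windows$resident]) {
  wrow <- windows[windows$animal_year == id, ]
  w <- structure(list(start_date = wrow$start_date,
                      end_date = wrow$end_date, duration = wrow$duration,
                      distance_km = wrow$distance_km, resident = FALSE),
                 class = "migration_window")
  cl <- speed_filter(tracks[[id]], cfg$speed_filter_kmh)
  wr <- seasonal_range(cl, w, landscape, "winter", level = cfg$kud_level,
                       cell = cfg$grid_res_m)
  sr <- seasonal_range(cl, w, landscape, "summer", level = cfg$kud_level,
                       cell = cfg$grid_res_m)
  mig <- cl[cl$t >= w$start_date & cl$t <= w$end_date, ]
  prof <- aggregate_dfp(days_from_peak(mig, landscape), animal_year = id)
  profiles[[id]] <- cbind(animal_year = id, prof$records)
  mism[[id]] <- data.frame(
    animal_year = id, dfp_start = range_mismatch(w, wr),
    dfp_end = range_mismatch(w, sr), mean_dfp = prof$mean_dfp,
    winter_area_km2 = wr$area_km2, summer_area_km2 = sr$area_km2)
}
write.csv(do.call(rbind, profiles), "results/surf_profiles.csv",
          row.names = FALSE)
mismatches <- do.call(rbind, mism)
write.csv(mismatches, "results/range_mismatches.csv", row.names = FALSE)
message(sprintf(
  "surfing: start mismatch %.0f to %.0f days; end mismatch %.0f to %.0f; SD %.1f -> %.1f",
  min(mismatches$dfp_start), max(mismatches$dfp_start),
  min(mismatches$dfp_end), max(mismatches$dfp_end),
  sd(mismatches$dfp_start), sd(mismatches$dfp_end)))

wave <- wave_propagation(landscape)
write.csv(wave$segments, "results/wave_segments.csv", row.names = FALSE)
neg <- wave$segments[wave$segments$direction == "negative", ]
message(sprintf(
  "wave propagation: %d segment(s); first negative segment ends at km %s",
  nrow(wave$segments),
  if (nrow(neg)) round(neg$km_end[1]) else "(none)"))
message("wrote results/surf_profiles.csv, range_mismatches.csv, wave_segments.csv")
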