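#' Workflow configuration
#'
#' Collects every numeric constant of the analysis in one place, so no
#' stage hard-codes a threshold. Defaults are the workflow's standard
#' values: 10.8 km/h GPS speed filter, 7-day compensation window, 3-day
#' minimum stopover residence, motion-variance gate at 8000, 99%/10% UD
#' isopleths for corridors/stopovers, 95% KUD seasonal ranges, and a
#' 150-m analysis grid.
#'
#' @param ... overrides of the defaults by name (unknown names error in
#'   [validate_config()]).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    speed_filter_kmh = 10.8,
    comp_window_days = 7,
    stopover_min_days = 3,
    variance_gate = 8000,
    ud_corridor_level = 0.99,
    ud_stopover_level = 0.10,
    kud_level = 0.95,
    grid_res_m = 150,
    max_bridge_lag_h = 8,
    location_error_m = 20,
    min_migration_delta_km2 = 100,
    n_animals = 60,
    departure_span = 100,
    fix_interval = 2,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Validate a workflow configuration
#'
#' Type/range checks every threshold and lists every deviation from the
#' default configuration. Unknown keys are an error.
#'
#' @param config a `run_config` (or plain named list).
#' @return list with `ok` (logical), `violations` (character) and
#'   `deviations` (character, keys differing from defaults).
#' @export
validate_config <- function(config) {
  defaults <- run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  v <- character(0)
  pos <- c("speed_filter_kmh", "stopover_min_days", "variance_gate",
           "grid_res_m", "max_bridge_lag_h", "location_error_m",
           "min_migration_delta_km2", "n_animals", "departure_span",
           "fix_interval")
  for (k in pos)
    if (!is.numeric(config[[k]]) || config[[k]] <= 0)
      v <- c(v, paste0(k, " must be positive"))
  if (!is.numeric(config$comp_window_days) || config$comp_window_days < 0)
    v <- c(v, "comp_window_days must be non-negative")
  for (k in c("ud_corridor_level", "ud_stopover_level", "kud_level"))
    if (!is.numeric(config[[k]]) || config[[k]] <= 0 || config[[k]] > 1)
      v <- c(v, paste0(k, " must be a fraction in (0, 1]"))
  dev <- names(defaults)[vapply(names(defaults), function(k)
    !isTRUE(all.equal(config[[k]], defaults[[k]])), logical(1))]
  list(ok = length(v) == 0, violations = v, deviations = dev)
}

#' Read / write a workflow configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a validated `run_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- do.call(run_config, yaml::read_yaml(path))
  chk <- validate_config(cfg)
  if (!chk$ok) stop("invalid config: ", paste(chk$violations, collapse = "; "))
  cfg
}

#' Run the full synthetic green-wave compensation workflow
#'
#' Executes simulate -> clean -> segment -> surf -> stopovers -> classify
#' -> summarize on a seeded synthetic landscape and cohort, logging one
#' line per stage with record counts. Animal-years that are resident,
#' truncated, or fail a stage are dropped with a tally.
#'
#' @param config a `run_config`.
#' @param outdir optional directory; when given, per-stage CSV/JSON/YAML
#'   artifacts are written there.
#' @param landscape optional pre-built `pheno_raster`; default builds one
#'   from the config seed.
#' @param cohort optional pre-built cohort from [make_cohort()].
#' @param quiet suppress stage log messages?
#' @return a report list: `records` (one row per retained animal-year),
#'   `summary` ([cohort_summary()] output), `ordinal` (`ordinal_fit` of
#'   full-compensation probability on absolute start mismatch), `wave`
#'   (`wave_profile`), `penalty` (penalty profile), `dropped` (named
#'   counts), `config`.
#' @export
run_all <- function(config = run_config(), outdir = NULL,
                    landscape = NULL, cohort = NULL, quiet = FALSE) {
  chk <- validate_config(config)
  if (!chk$ok) stop("invalid config: ", paste(chk$violations, collapse = "; "))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(landscape))
    landscape <- make_landscape(landscape_spec(seed = config$seed))
  if (is.null(cohort))
    cohort <- make_cohort(landscape, n_animals = config$n_animals,
                          departure_span = config$departure_span,
                          fix_interval = config$fix_interval,
                          seed = config$seed + 1L)
  say("simulate: %d cells, %d animal-years", nrow(landscape),
      length(cohort$tracks))

  dropped <- c(resident = 0L, truncated = 0L, stage_error = 0L,
               variance_gate = 0L, filtered_fixes = 0L)
  rows <- list()
  for (id in names(cohort$tracks)) {
    rec <- tryCatch({
      tr <- cohort$tracks[[id]]
      if (isTRUE(attr(tr, "truth")$truncated)) {
        dropped["truncated"] <- dropped["truncated"] + 1L
        next
      }
      cl <- speed_filter(tr, config$speed_filter_kmh)
      dropped["filtered_fixes"] <- dropped["filtered_fixes"] +
        attr(cl, "removed")
      win <- segment_migration(nsd(cl), track = cl,
                               min_delta_km2 = config$min_migration_delta_km2)
      if (isTRUE(win$resident)) {
        dropped["resident"] <- dropped["resident"] + 1L
        next
      }
      wr <- seasonal_range(cl, win, landscape, "winter",
                           level = config$kud_level,
                           cell = config$grid_res_m)
      sr <- seasonal_range(cl, win, landscape, "summer",
                           level = config$kud_level,
                           cell = config$grid_res_m)
      mig <- cl[cl$t >= win$start_date & cl$t <= win$end_date, ,
                drop = FALSE]
      attr(mig, "fix_interval") <- attr(cl, "fix_interval")
      prof <- aggregate_dfp(days_from_peak(mig, landscape),
                            animal_year = id)
      s2 <- estimate_motion_variance(mig, config$location_error_m,
                                     config$max_bridge_lag_h)
      stop_days <- NA_real_
      if (variance_gate(s2, config$variance_gate)) {
        ud <- bbmm_ud(mig, as.numeric(s2), cell = config$grid_res_m,
                      location_error = config$location_error_m,
                      max_lag_h = config$max_bridge_lag_h)
        stop_days <- stopover_days(mig, ud,
                                   level = config$ud_stopover_level,
                                   min_days = config$stopover_min_days)$total_days
      } else {
        dropped["variance_gate"] <- dropped["variance_gate"] + 1L
      }
      data.frame(animal_year = id,
                 start_date = win$start_date, end_date = win$end_date,
                 duration = win$duration, distance_km = win$distance_km,
                 rate = movement_rate(win),
                 dfp_start = range_mismatch(win, wr),
                 dfp_end = range_mismatch(win, sr),
                 mean_dfp = prof$mean_dfp,
                 motion_variance = as.numeric(s2),
                 stopover_days = stop_days)
    }, error = function(e) {
      dropped["stage_error"] <<- dropped["stage_error"] + 1L
      NULL
    })
    if (!is.null(rec)) rows[[id]] <- rec
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (is.null(records) || nrow(records) < 4)
    stop("fewer than 4 usable animal-years; cannot classify cohort")
  say("segment+surf+stopovers: %d/%d animal-years retained",
      nrow(records), length(cohort$tracks))

  records <- merge(records, cohort$covariates, by = "animal_year",
                   sort = TRUE)
  records$standardized_start <- standardize_start(records$start_date,
                                                  records$year)
  records$timing_class <- classify_timing(records$standardized_start)
  records$comp_class <- classify_compensation(records$dfp_start,
                                              records$dfp_end,
                                              config$comp_window_days)
  say("classify: %s",
      paste(names(table(records$comp_class)), table(records$comp_class),
            sep = "=", collapse = " "))

  ord <- fit_ordinal(records$comp_class, abs(records$dfp_start))
  summ <- cohort_summary(records)
  wave <- wave_propagation(landscape)
  pen <- penalty_profile(landscape)
  say("summarize: ordinal beta=%.3f (OR %.2f), wave slope %.3f d/km",
      ord$beta, exp(ord$beta), wave$overall$slope)

  report <- list(records = records, summary = summ, ordinal = ord,
                 wave = wave, penalty = pen, dropped = dropped,
                 config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(outdir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$class_means,
                     file.path(outdir, "class_means.csv"),
                     row.names = FALSE)
    utils::write.csv(wave$segments, file.path(outdir, "wave_segments.csv"),
                     row.names = FALSE)
    utils::write.csv(pen$per_quarter,
                     file.path(outdir, "penalty_quarters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(beta = ord$beta, ci95 = ord$ci95, cutpoints = ord$cutpoints,
           loglik = ord$loglik, odds_ratio = exp(ord$beta), n = ord$n),
      file.path(outdir, "ordinal_fit.json"), auto_unbox = TRUE,
      digits = NA)
    yaml::write_yaml(
      list(config = unclass(config), dropped = as.list(dropped),
           n_records = nrow(records),
           r_version = as.character(getRversion())),
      file.path(outdir, "run_log.yaml"))
  }
  invisible(report)
}
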