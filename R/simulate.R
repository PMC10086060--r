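#' Specification of a simulated migrating agent
#'
#' Behavior rules for one agent-year. The agent departs its winter range
#' at a fixed offset from local peak green-up, then each day senses its
#' mismatch with the wave (Days-From-Peak at its current position,
#' positive = behind the wave) and sets its daily displacement to
#' `clamp(base_speed + mismatch_gain * DFP, 0, max_speed)`. Optionally it
#' pauses (a stopover) whenever it is more than `stopover_ahead_days`
#' ahead of the local peak — waiting for the wave to catch up.
#'
#' @param departure_offset days relative to peak green-up at the departure
#'   cell (negative = departs ahead of the wave).
#' @param base_speed km/day when perfectly surfing.
#' @param mismatch_gain km/day of speed-up per day behind the wave
#'   (0 = mismatch-blind agent).
#' @param max_speed km/day ceiling.
#' @param stopover_ahead_days the agent is pause-prone whenever locally
#'   more than this many days ahead of peak; `NA` disables stopovers.
#' @param pause_bout_days mean length (days) of a stopover bout: while
#'   ahead, a paused agent resumes moving with probability
#'   `1/pause_bout_days` per day (and immediately once no longer ahead).
#' @param move_bout_days mean length (days) of a movement bout while
#'   ahead: a moving agent starts a pause with probability
#'   `1/move_bout_days` per day. Bout structure makes pauses multi-day
#'   residences at one site — stopovers — rather than daily stop-and-go,
#'   and lets strongly-ahead migrants progress slowly instead of stalling
#'   on the winter range.
#' @param min_speed km/day floor applied on moving days while the
#'   stopover rule is active (ignored when `stopover_ahead_days = NA`).
#' @param fix_interval GPS fix schedule, hours (1, 2 or 3, matching collar
#'   programs).
#' @param gps_noise_sd positional noise per fix, meters.
#' @param site_wander_sd SD (meters) of a day-level positional offset,
#'   the small-scale ranging behavior that gives seasonal ranges and
#'   stopovers spatial extent.
#' @param seed integer seed for this agent's noise.
#' @return object of class `agent_spec`.
#' @export
agent_spec <- function(departure_offset = 0, base_speed = 6,
                       mismatch_gain = 0.15, max_speed = 12,
                       stopover_ahead_days = 2, pause_bout_days = 5,
                       move_bout_days = 3, min_speed = 4, fix_interval = 2,
                       gps_noise_sd = 15, site_wander_sd = 150, seed = 1L) {
  stopifnot(base_speed > 0, max_speed >= base_speed,
            fix_interval %in% c(1, 2, 3), gps_noise_sd >= 0,
            site_wander_sd >= 0, pause_bout_days >= 1, move_bout_days >= 1,
            min_speed >= 0)
  structure(list(departure_offset = departure_offset,
                 base_speed = base_speed, mismatch_gain = mismatch_gain,
                 max_speed = max_speed,
                 stopover_ahead_days = stopover_ahead_days,
                 pause_bout_days = pause_bout_days,
                 move_bout_days = move_bout_days, min_speed = min_speed,
                 fix_interval = fix_interval, gps_noise_sd = gps_noise_sd,
                 site_wander_sd = site_wander_sd,
                 seed = as.integer(seed)),
            class = "agent_spec")
}

#' Simulate one agent's GPS track along a corridor
#'
#' Produces time-ordered fixes at the agent's fix schedule: a stationary
#' pre-departure period on the winter range, mismatch-modulated daily
#' movement up the corridor, and a stationary summer-range period after
#' arrival at the corridor end. If the agent is still en route after
#' `n_days` the track is truncated and flagged.
#'
#' @param landscape a `pheno_raster` from [make_landscape()].
#' @param agent an [agent_spec()].
#' @param n_days days simulated after departure.
#' @param pre_days stationary winter-range days before departure.
#' @param start_km departure position along the corridor, km.
#' @param animal_id identifier stored with the track.
#' @return a `deer_track`: data frame `animal_id, t, x, y` (t = continuous
#'   day-of-year, x/y projected meters with the corridor along +y), with
#'   attributes `fix_interval`, `animal_year`, and `truth` (departure day,
#'   first moving day, arrival day, paused days, truncation flag).
#' @export
simulate_deer <- function(landscape, agent, n_days = 160, pre_days = 15,
                          start_km = 0, animal_id = "a1") {
  stopifnot(inherits(landscape, "pheno_raster"), inherits(agent, "agent_spec"))
  spec <- attr(landscape, "spec")
  depart <- peak_date_at(landscape, max(start_km, spec$cell_size / 2)) +
    agent$departure_offset
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(agent$seed)

  nf <- as.integer(24 / agent$fix_interval)
  days <- seq(depart - pre_days, depart + n_days - 1)
  # day-level ranging offsets; frozen while paused (stopover site fidelity)
  wx <- stats::rnorm(length(days), 0, agent$site_wander_sd)
  wy <- stats::rnorm(length(days), 0, agent$site_wander_sd)
  pos <- start_km
  t_all <- pos_all <- x_off <- y_off <- numeric(0)
  first_move <- arrival <- NA_real_
  paused_days <- 0L
  paused <- FALSE

  for (k in seq_along(days)) {
    d <- days[k]
    moving <- FALSE
    speed <- 0
    if (d >= depart && is.na(arrival)) {
      dfp <- d - peak_date_at(landscape, pos)
      if (!is.na(agent$stopover_ahead_days)) {
        ahead <- dfp < -agent$stopover_ahead_days
        if (paused) {
          paused <- ahead &&
            stats::runif(1) > 1 / agent$pause_bout_days
        } else {
          paused <- ahead && stats::runif(1) < 1 / agent$move_bout_days
        }
      }
      if (paused) {
        paused_days <- paused_days + 1L
        if (k > 1) {
          wx[k] <- wx[k - 1]
          wy[k] <- wy[k - 1]
        }
      } else {
        speed <- min(max(agent$base_speed + agent$mismatch_gain * dfp, 0),
                     agent$max_speed)
        if (!is.na(agent$stopover_ahead_days))
          speed <- min(max(speed, agent$min_speed), agent$max_speed)
        moving <- speed > 0
        if (moving && is.na(first_move)) first_move <- d
      }
    }
    frac <- (seq_len(nf) - 1) / nf
    t_all <- c(t_all, d + frac)
    pos_all <- c(pos_all, pmin(pos + speed * frac, spec$corridor_length))
    x_off <- c(x_off, rep(wx[k], nf))
    y_off <- c(y_off, rep(wy[k], nf))
    pos <- min(pos + speed, spec$corridor_length)
    if (is.na(arrival) && pos >= spec$corridor_length) arrival <- d + 1
  }

  truncated <- is.na(arrival)
  if (truncated)
    warning("agent still en route after n_days; track truncated",
            call. = FALSE)
  n <- length(t_all)
  out <- data.frame(
    animal_id = animal_id, t = t_all,
    x = x_off + stats::rnorm(n, 0, agent$gps_noise_sd),
    y = pos_all * 1000 + y_off + stats::rnorm(n, 0, agent$gps_noise_sd))
  structure(out, class = c("deer_track", "data.frame"),
            fix_interval = agent$fix_interval, animal_year = animal_id,
            truth = list(departure_day = depart, first_move_day = first_move,
                         arrival_day = arrival, paused_days = paused_days,
                         truncated = truncated))
}

#' @export
print.deer_track <- function(x, ...) {
  cat(sprintf("<deer_track> %s: %d fixes every %d h, days %.1f-%.1f\n",
              attr(x, "animal_year"), nrow(x), attr(x, "fix_interval"),
              min(x$t), max(x$t)))
  invisible(x)
}

#' Simulate a cohort of agents with asynchronous departures
#'
#' Draws departure offsets from a uniform window (default spanning 100
#' days, emulating winter-range departures from two months ahead to ~1.5
#' months behind the green wave) and a mixture of behavior types:
#' `compensator` agents speed up when behind and pause when ahead;
#' `non` agents are mismatch-blind (no gain, no stopover rule) with
#' idiosyncratic speeds, so they drift relative to the wave.
#'
#' @param landscape a `pheno_raster`.
#' @param n_animals cohort size (>= 4 so timing quartiles are nonempty).
#' @param departure_span width (days) of the uniform departure-offset
#'   window, centered on 0.
#' @param mixture named proportions for behavior types
#'   `c(compensator = , non = )`; must sum to 1.
#' @param fix_interval collar schedule in hours for the whole cohort.
#' @param n_days,pre_days passed to [simulate_deer()].
#' @param seed integer master seed; agent seeds are derived from it.
#' @return list with `tracks` (named list of `deer_track`) and
#'   `covariates` (data frame: animal_year, year, age, condition,
#'   behavior, departure_offset).
#' @export
make_cohort <- function(landscape, n_animals = 60, departure_span = 100,
                        mixture = c(compensator = 0.85, non = 0.15),
                        fix_interval = 2, n_days = 170, pre_days = 15,
                        seed = 1L) {
  stopifnot(n_animals >= 4, departure_span >= 0,
            abs(sum(mixture) - 1) < 1e-8,
            all(names(mixture) %in% c("compensator", "non")))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  offsets <- stats::runif(n_animals, -departure_span / 2, departure_span / 2)
  behavior <- sample(names(mixture), n_animals, replace = TRUE,
                     prob = mixture)
  age <- sample(1:13, n_animals, replace = TRUE)
  condition <- round(stats::runif(n_animals, 4, 12), 1)  # % IFBFat-like
  agent_seeds <- sample.int(.Machine$integer.max, n_animals)

  tracks <- vector("list", n_animals)
  ids <- sprintf("deer%03d", seq_len(n_animals))
  for (i in seq_len(n_animals)) {
    ag <- if (behavior[i] == "compensator") {
      agent_spec(departure_offset = offsets[i],
                 fix_interval = fix_interval, seed = agent_seeds[i])
    } else {
      agent_spec(departure_offset = offsets[i],
                 base_speed = stats::runif(1, 2.5, 8), mismatch_gain = 0,
                 stopover_ahead_days = NA, fix_interval = fix_interval,
                 seed = agent_seeds[i])
    }
    tracks[[i]] <- suppressWarnings(
      simulate_deer(landscape, ag, n_days = n_days, pre_days = pre_days,
                    animal_id = ids[i]))
  }
  names(tracks) <- ids
  list(tracks = tracks,
       covariates = data.frame(animal_year = ids, year = 2017L, age = age,
                               condition = condition, behavior = behavior,
                               departure_offset = offsets))
}

#' Write / read tracks as Movebank-style CSV
#'
#' Columns `individual-local-identifier, timestamp, x, y` with timestamps
#' in ISO-8601 UTC; the fix schedule is stored in a
#' `# fix-interval-hours:` header comment. Day-of-year is anchored to the
#' year given (the simulator's continuous day-of-year maps to UTC time).
#'
#' @param tracks a `deer_track` or list of them.
#' @param path output file.
#' @param year calendar year used to anchor day-of-year timestamps.
#' @return `path` (write); a named list of `deer_track` (read).
#' @export
write_tracks_csv <- function(tracks, path, year = 2017) {
  if (inherits(tracks, "deer_track")) tracks <- list(tracks)
  fi <- attr(tracks[[1]], "fix_interval")
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(`individual-local-identifier` = tr$animal_id,
               timestamp = format(
                 as.POSIXct((tr$t - 1) * 86400,
                            origin = sprintf("%d-01-01", year), tz = "UTC"),
                 "%Y-%m-%d %H:%M:%S"),
               x = round(tr$x, 2), y = round(tr$y, 2),
               check.names = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fix-interval-hours: %d", fi), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, year = 2017) {
  hdr <- readLines(path, n = 1)
  fi <- as.integer(sub(".*: *", "", hdr))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  tt <- as.POSIXct(df$timestamp, tz = "UTC")
  df$t <- as.numeric(difftime(tt, as.POSIXct(sprintf("%d-01-01", year),
                                             tz = "UTC"), units = "days")) + 1
  ids <- unique(df$`individual-local-identifier`)
  out <- lapply(ids, function(id) {
    sub <- df[df$`individual-local-identifier` == id, ]
    structure(data.frame(animal_id = id, t = sub$t, x = sub$x, y = sub$y),
              class = c("deer_track", "data.frame"),
              fix_interval = fi, animal_year = id, truth = NULL)
  })
  stats::setNames(out, ids)
}
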