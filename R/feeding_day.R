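#' Behavioral mode from appetite and feed presence
#'
#' A fish is in feeding mode exactly when feed is present in the tank and
#' its intake so far today is below its satiation cap; otherwise it is in
#' standard mode.
#'
#' @param intake Intake so far today, grams (vectorized).
#' @param smax Satiation cap, grams.
#' @param feed_present Is any live pellet in the tank?
#' @return Character vector, `"feeding"` or `"standard"`.
#' @export
select_mode <- function(intake, smax, feed_present) {
  ifelse(feed_present & intake < smax, "feeding", "standard")
}

#' Simulate one feeding day
#'
#' Runs the inner loop of one feeding bout (default 1000 s at dt =
#' 0.025 s): every step recomputes behavioral modes, perception and
#' forces, integrates the motion of all fish synchronously, sinks the
#' pellets and resolves contact consumption.  Per-fish intake is reset to
#' zero at the start of the day; the satiation cap is computed once from
#' start-of-day mass (mass is constant within a day, growth applies at
#' day end).
#'
#' @param school A `fish_school` from [init_school()].
#' @param config An `experiment_config`.
#' @param day Day index stamped on the result.
#' @param pellets A `pellet_field`, or `NULL` to spawn the daily ration
#'   via [daily_ration()] and [spawn_pellets()].
#' @param engine `"cpp"` (compiled, production) or `"r"` (reference
#'   implementation; identical physics, practical only for micro
#'   scenarios).  The two engines draw random numbers in different
#'   patterns, so their stochastic trajectories differ; each is
#'   deterministic under a fixed seed.
#' @param stop_when_consumed End the loop as soon as the last pellet is
#'   eaten (final positions then reflect that earlier time; intended for
#'   daily-randomization runs and completion-time measurements).
#' @param record_events Keep the per-pellet intake event log.
#' @return A list of class `feeding_day_result`: `day`, `intake` (g per
#'   fish), `pellets_per_fish`, `pellets_spawned`, `pellets_eaten`,
#'   `completion_time` (s, `NA` if feed remained), `school` (final
#'   state), `events`, `max_speed_excess` (diagnostic: worst post-step
#'   speed-cap violation, expected 0), `steps_run`.
#' @export
run_feeding_day <- function(school, config, day = 1L, pellets = NULL,
                            engine = c("cpp", "r"),
                            stop_when_consumed = FALSE,
                            record_events = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(school, "data.frame"), nrow(school) >= 1L)
  school$intake <- 0
  school$pellets_eaten <- 0L
  if (is.null(pellets)) {
    ration <- daily_ration(school$mass, config)
    pellets <- spawn_pellets(ration, config$method, config$tank,
                             config$pellet_mass)
  }
  smax <- smax_intake(school$mass, config$smax_fraction)
  n_steps <- floor(config$feeding_duration / config$dt + 1e-9)
  spawned <- nrow(pellets)

  if (engine == "cpp") {
    res <- run_feeding_day_cpp(
      pos = cbind(school$x, school$y, school$z),
      vel = cbind(school$vx, school$vy, school$vz),
      mass = school$mass, tl = school$tl, smax = smax,
      pellet_xyz = cbind(pellets$x, pellets$y, pellets$z),
      pellet_alive = pellets$alive,
      par = engine_params(config),
      n_steps = as.integer(n_steps),
      stop_when_consumed = isTRUE(stop_when_consumed),
      record_events = isTRUE(record_events))
    school$x <- res$pos[, 1]; school$y <- res$pos[, 2]; school$z <- res$pos[, 3]
    school$vx <- res$vel[, 1]; school$vy <- res$vel[, 2]; school$vz <- res$vel[, 3]
    school$intake <- res$intake
    school$pellets_eaten <- res$pellets_eaten
    school$mode <- ifelse(res$mode_feeding, "feeding", "standard")
    pellets$alive <- res$pellet_alive
    pellets$z <- res$pellet_z
    events <- if (isTRUE(record_events))
      data.frame(time = res$events[, 1],
                 fish_id = as.integer(res$events[, 2]),
                 pellet_id = as.integer(res$events[, 3]))
      else NULL
    completion <- if (res$completion_step > 0) res$completion_step * config$dt
      else NA_real_
    max_excess <- res$max_speed_excess
    steps_run <- res$steps_run
  } else {
    events <- list()
    completion <- NA_real_
    steps_run <- 0L
    for (s in seq_len(n_steps)) {
      st <- step_school(school, pellets, config, smax,
                        time = (s - 1L) * config$dt)
      school <- st$school; pellets <- st$pellets
      if (nrow(st$events)) events[[length(events) + 1L]] <- st$events
      steps_run <- s
      if (!any(pellets$alive) && is.na(completion) && nrow(pellets) > 0)
        completion <- s * config$dt
      if (stop_when_consumed && !any(pellets$alive)) break
      if (!all(is.finite(c(school$x, school$vx))))
        stop("non-finite state at step ", s, call. = FALSE)
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(time = numeric(), fish_id = integer(), pellet_id = integer())
    if (!record_events) events <- NULL
    max_excess <- 0
  }

  eaten <- sum(school$pellets_eaten)
  stopifnot(isTRUE(all.equal(sum(school$intake), eaten * config$pellet_mass)))
  structure(list(
    day = as.integer(day),
    intake = school$intake,
    pellets_per_fish = school$pellets_eaten,
    pellets_spawned = spawned,
    pellets_eaten = eaten,
    completion_time = completion,
    school = school,
    events = events,
    max_speed_excess = max_excess,
    steps_run = steps_run
  ), class = "feeding_day_result")
}

#' @export
print.feeding_day_result <- function(x, ...) {
  cat(sprintf(
    "<feeding_day_result> day %d: %d/%d pellets eaten (%.3f g), completion %s\n",
    x$day, x$pellets_eaten, x$pellets_spawned, sum(x$intake),
    if (is.na(x$completion_time)) "-" else sprintf("%.2f s", x$completion_time)))
  invisible(x)
}

# flatten config into the scalar list the C++ engine expects
engine_params <- function(config) {
  w <- config$weights
  list(
    dt = config$dt,
    radius = config$tank$radius,
    depth = config$tank$depth,
    w1 = w$w1, w2 = w$w2, w3 = w$w3, w4 = w$w4,
    w5_standard = w$w5_standard, w5_feeding = w$w5_feeding, w6 = w$w6,
    cv_standard = w$cv_standard, cv_feeding = w$cv_feeding,
    sink_speed = config$sink_speed,
    pellet_mass = config$pellet_mass,
    pellet_radius = config$pellet_diameter / 2,
    contact_radius_factor = config$contact_radius_factor,
    fov_radius_factor = config$fov_radius_factor,
    cos_dead_zone = cos(config$dead_zone_half_angle * pi / 180),
    force_scale = config$force_scale,
    isotropic = config$isotropic_random,
    clamp_eps = CLAMP_EPS
  )
}
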