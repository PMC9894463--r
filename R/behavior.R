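norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) c(0, 0, 0) else v / n
}

random_unit <- function(isotropic = FALSE) {
  repeat {
    u <- if (isotropic) stats::rnorm(3) else stats::runif(3, -1, 1)
    n2 <- sum(u * u)
    if (n2 > 1e-24) return(u / sqrt(n2))
  }
}

#' Perception: field of view, nearest neighbor, boundary and pellet
#'
#' The field of view is a sphere of radius `fov_radius_factor * TL`
#' (default twice the focal fish's total length) minus a rear "dead
#' space" cone of the given half angle (default 30 degrees) about the
#' direction opposite the focal velocity.  When the focal fish is
#' stationary the dead cone is undefined and treated as absent.  Feed is
#' detected regardless of the field of view; the nearest boundary point is
#' the closest of the cylindrical wall, the bottom and the surface, and is
#' reported only when it lies within the field-of-view sphere.
#'
#' @param school A `fish_school` data frame.
#' @param i Row index of the focal fish.
#' @param config An `experiment_config`.
#' @param pellets Optional `pellet_field`.
#' @return A list with `neighbor_ids` (row indices in view, increasing),
#'   `nearest_neighbor_id` (row index or `NA`), `nearest_boundary_point`
#'   (3-vector or `NULL`), `nearest_pellet_position` (3-vector or `NULL`).
#' @export
perceive <- function(school, i, config, pellets = NULL) {
  xi <- c(school$x[i], school$y[i], school$z[i])
  vi <- c(school$vx[i], school$vy[i], school$vz[i])
  fov <- config$fov_radius_factor * school$tl[i]
  spd <- norm3(vi)
  cosdz <- cos(config$dead_zone_half_angle * pi / 180)
  n <- nrow(school)
  in_view <- logical(n)
  d2s <- rep(Inf, n)
  for (j in seq_len(n)) {
    if (j == i) next
    d <- c(school$x[j], school$y[j], school$z[j]) - xi
    d2 <- sum(d * d)
    if (d2 > fov^2) next
    if (spd > 0 && d2 > 0) {
      dot <- sum(d * vi)
      # inside rear cone: angle between d and -v strictly below half angle
      if (dot < 0 && dot^2 > cosdz^2 * d2 * spd^2) next
    }
    in_view[j] <- TRUE
    d2s[j] <- d2
  }
  ids <- which(in_view)
  nn <- if (length(ids)) ids[which.min(d2s[ids])] else NA_integer_
  # boundary candidates: wall (radial projection), bottom, surface
  r <- sqrt(xi[1]^2 + xi[2]^2)
  bound <- NULL
  cand_d <- c(wall = if (r > 1e-12) config$tank$radius - r else config$tank$radius,
              bottom = xi[3], surface = config$tank$depth - xi[3])
  which_b <- names(cand_d)[which.min(cand_d)]
  if (min(cand_d) <= fov) {
    bound <- switch(which_b,
      wall = c(xi[1] * config$tank$radius / r, xi[2] * config$tank$radius / r, xi[3]),
      bottom = c(xi[1], xi[2], 0),
      surface = c(xi[1], xi[2], config$tank$depth))
  }
  pel <- NULL
  if (!is.null(pellets) && any(pellets$alive)) {
    live <- which(pellets$alive)
    pd2 <- (pellets$x[live] - xi[1])^2 + (pellets$y[live] - xi[2])^2 +
      (pellets$z[live] - xi[3])^2
    k <- live[which.min(pd2)]
    pel <- c(pellets$x[k], pellets$y[k], pellets$z[k])
  }
  list(neighbor_ids = ids, nearest_neighbor_id = nn,
       nearest_boundary_point = bound, nearest_pellet_position = pel)
}

#' Rule forces of the schooling kernel
#'
#' Six steering rules, each a vector of magnitude equal to its weight (or
#' zero when the rule has no target): separation repels from the nearest
#' in-view neighbor, cohesion attracts towards the in-view centroid,
#' alignment steers towards the in-view mean velocity, boundary avoidance
#' repels from the nearest in-view tank boundary point, feed attraction
#' pulls towards the nearest live pellet (regardless of the field of
#' view; weight 0 in standard mode), and random movement is a uniformly
#' drawn direction.  The total swimming force is their plain sum.
#'
#' @param school,i,config,pellets As in [perceive()].
#' @param percept A perception list from [perceive()].
#' @param w Rule weight.
#' @return A numeric 3-vector (force).
#' @name rule_forces
NULL

#' @rdname rule_forces
#' @export
separation_force <- function(school, i, percept, w) {
  j <- percept$nearest_neighbor_id
  if (is.na(j)) return(c(0, 0, 0))
  d <- c(school$x[i] - school$x[j], school$y[i] - school$y[j],
         school$z[i] - school$z[j])
  if (norm3(d) == 0) {
    warning("coincident fish positions; separation falls back to a random direction")
    return(w * random_unit())
  }
  w * unit3(d)
}

#' @rdname rule_forces
#' @export
cohesion_force <- function(school, i, percept, w) {
  ids <- percept$neighbor_ids
  if (!length(ids)) return(c(0, 0, 0))
  ctr <- c(mean(school$x[ids]), mean(school$y[ids]), mean(school$z[ids]))
  d <- ctr - c(school$x[i], school$y[i], school$z[i])
  w * unit3(d)  # zero vector when focal sits exactly at the centroid
}

#' @rdname rule_forces
#' @export
alignment_force <- function(school, i, percept, w) {
  ids <- percept$neighbor_ids
  if (!length(ids)) return(c(0, 0, 0))
  vbar <- c(mean(school$vx[ids]), mean(school$vy[ids]), mean(school$vz[ids]))
  d <- vbar - c(school$vx[i], school$vy[i], school$vz[i])
  w * unit3(d)
}

#' @rdname rule_forces
#' @export
boundary_force <- function(school, i, percept, w, tank) {
  b <- percept$nearest_boundary_point
  if (is.null(b)) return(c(0, 0, 0))
  xi <- c(school$x[i], school$y[i], school$z[i])
  d <- xi - b
  if (norm3(d) > 0) return(w * unit3(d))
  # sitting exactly on the boundary: use the inward normal
  r <- sqrt(xi[1]^2 + xi[2]^2)
  if (abs(b[3] - 0) < 1e-15 && xi[3] == 0) return(w * c(0, 0, 1))
  if (abs(b[3] - tank$depth) < 1e-15 && xi[3] == tank$depth) return(w * c(0, 0, -1))
  if (r > 0) w * c(-xi[1] / r, -xi[2] / r, 0) else c(0, 0, 0)
}

#' @rdname rule_forces
#' @export
feed_force <- function(school, i, percept, w) {
  p <- percept$nearest_pellet_position
  if (is.null(p) || w == 0) return(c(0, 0, 0))
  d <- p - c(school$x[i], school$y[i], school$z[i])
  w * unit3(d)
}

#' @rdname rule_forces
#' @param w6 Random-movement weight.
#' @param isotropic Draw uniformly on the sphere instead of normalizing a
#'   cube-uniform draw (the literal scheme, kept as the default, slightly
#'   over-represents corner directions).
#' @export
random_force <- function(w6, isotropic = FALSE) {
  w6 * random_unit(isotropic)
}

#' Total swimming force on one fish
#'
#' Plain sum of the six rule forces for the focal fish in its current
#' behavioral mode.  The feed weight is `w5_feeding` in feeding mode and
#' `w5_standard` (default 0) otherwise.
#'
#' @inheritParams perceive
#' @param f6 Optional pre-drawn random-movement force (3-vector); when
#'   `NULL` a fresh direction is drawn from the RNG stream.
#' @return A numeric 3-vector.
#' @export
total_force <- function(school, i, config, pellets = NULL, f6 = NULL) {
  percept <- perceive(school, i, config, pellets)
  w <- config$weights
  w5 <- if (school$mode[i] == "feeding") w$w5_feeding else w$w5_standard
  if (is.null(f6)) f6 <- random_force(w$w6, config$isotropic_random)
  separation_force(school, i, percept, w$w1) +
    cohesion_force(school, i, percept, w$w2) +
    alignment_force(school, i, percept, w$w3) +
    boundary_force(school, i, percept, w$w4, config$tank) +
    feed_force(school, i, percept, w5) +
    f6
}

#' Cap a velocity at the mode-dependent maximum speed
#'
#' Swimming ability is bounded: `|v|max = Cv * TL` with `Cv` depending on
#' the behavioral mode (cruising vs feeding burst).  Velocities above the
#' cap are rescaled to the cap, preserving direction.
#'
#' @param v Velocity 3-vector, m/s.
#' @param mode `"standard"` or `"feeding"`.
#' @param tl Total length, metres.
#' @param weights A [behavior_weights()].
#' @return The (possibly rescaled) velocity.
#' @export
cap_speed <- function(v, mode, tl, weights) {
  cv <- if (mode == "feeding") weights$cv_feeding else weights$cv_standard
  vmax <- cv * tl
  s <- norm3(v)
  if (s > vmax) v * (vmax / s) else v
}

# interior clamp distance (m): fish centres are kept this far off the walls
CLAMP_EPS <- 1e-3

clamp_to_tank <- function(x, v, tank) {
  r <- sqrt(x[1]^2 + x[2]^2)
  rmax <- tank$radius - CLAMP_EPS
  if (r > rmax) {
    x[1:2] <- x[1:2] * (rmax / r)
    er <- c(x[1], x[2], 0) / rmax
    vr <- sum(v * er)
    if (vr > 0) v <- v - vr * er
  }
  if (x[3] < CLAMP_EPS) {
    x[3] <- CLAMP_EPS
    if (v[3] < 0) v[3] <- 0
  }
  if (x[3] > tank$depth - CLAMP_EPS) {
    x[3] <- tank$depth - CLAMP_EPS
    if (v[3] > 0) v[3] <- 0
  }
  list(x = x, v = v)
}

#' Semi-implicit Euler step for one fish
#'
#' Newtonian update with the velocity refreshed first and the position
#' advanced with the new (capped) velocity:
#' `a = F / (m / force_scale)`, `v <- cap(v + a dt)`, `x <- x + v dt`.
#' With the default `force_scale = 1000` the body mass in grams acts as a
#' mass in kilograms under newton-scale rule weights; transient
#' accelerations are then large and the dynamics are governed by the
#' speed cap.  After the update the position is clamped to the tank
#' interior (1 mm inside every boundary) with the outward velocity
#' component zeroed.
#'
#' @param x,v Position (m) and velocity (m/s) 3-vectors.
#' @param force Swimming force 3-vector.
#' @param mass Body mass, grams.
#' @param mode,tl,weights Passed to [cap_speed()].
#' @param dt Time step, seconds.
#' @param tank A [tank_geometry()].
#' @param force_scale Gram-to-inertial-mass divisor (see
#'   [experiment_config()]).
#' @return A list with updated `x` and `v`.
#' @export
integrate_step <- function(x, v, force, mass, mode, tl, weights, dt, tank,
                           force_scale = 1000) {
  if (!all(is.finite(force))) stop("non-finite swimming force", call. = FALSE)
  a <- force / (mass / force_scale)
  v <- cap_speed(v + a * dt, mode, tl, weights)
  x <- x + v * dt
  clamp_to_tank(x, v, tank)
}

#' Record a short swimming trajectory
#'
#' Runs the reference engine for `n_steps` steps and returns the
#' per-step kinematic state of every fish in long format, suitable for
#' path plots or columnar text export.  Intended for short diagnostic
#' windows (the reference engine is not built for full-day runs).
#'
#' @inheritParams step_school
#' @param n_steps Number of steps to record.
#' @param every Keep every `every`-th step (1 = all).
#' @return A data frame `step, time, id, x, y, z, vx, vy, vz, mode`.
#' @export
record_trajectory <- function(school, config, n_steps, pellets = NULL,
                              every = 1L,
                              smax = smax_intake(school$mass,
                                                 config$smax_fraction)) {
  out <- vector("list", n_steps %/% every + 1L)
  keep <- function(s, sc) data.frame(
    step = s, time = s * config$dt, id = sc$id, x = sc$x, y = sc$y,
    z = sc$z, vx = sc$vx, vy = sc$vy, vz = sc$vz, mode = sc$mode)
  k <- 0L
  for (s in seq_len(n_steps)) {
    st <- step_school(school, pellets, config, smax,
                      time = (s - 1L) * config$dt)
    school <- st$school; pellets <- st$pellets
    if (s %% every == 0L) { k <- k + 1L; out[[k]] <- keep(s, school) }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Advance the whole school by one time step (reference engine)
#'
#' One synchronous step of the coupled kernel in the fixed intra-step
#' order: behavioral modes -> perception -> forces (from the pre-step
#' state of all fish) -> integration -> pellet sinking -> contact
#' consumption.  This pure-R implementation is the brute-force oracle for
#' the compiled engine and the workhorse for micro-fixtures; use
#' [run_feeding_day()] with `engine = "cpp"` for production runs.
#'
#' @param school A `fish_school`.
#' @param pellets A `pellet_field` or `NULL`.
#' @param config An `experiment_config`.
#' @param smax Per-fish satiation caps, grams.
#' @param time Simulation time at the start of the step, seconds.
#' @param f6 Optional `n x 3` matrix of pre-drawn random-movement forces.
#' @return A list with `school`, `pellets`, `events`.
#' @export
step_school <- function(school, pellets, config, smax, time = 0, f6 = NULL) {
  n <- nrow(school)
  feed_present <- !is.null(pellets) && any(pellets$alive)
  school$mode <- ifelse(feed_present & school$intake < smax,
                        "feeding", "standard")
  forces <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    fi <- if (is.null(f6)) NULL else f6[i, ]
    forces[i, ] <- total_force(school, i, config, pellets, f6 = fi)
  }
  for (i in seq_len(n)) {
    st <- integrate_step(
      x = c(school$x[i], school$y[i], school$z[i]),
      v = c(school$vx[i], school$vy[i], school$vz[i]),
      force = forces[i, ], mass = school$mass[i], mode = school$mode[i],
      tl = school$tl[i], weights = config$weights, dt = config$dt,
      tank = config$tank, force_scale = config$force_scale)
    school$x[i] <- st$x[1]; school$y[i] <- st$x[2]; school$z[i] <- st$x[3]
    school$vx[i] <- st$v[1]; school$vy[i] <- st$v[2]; school$vz[i] <- st$v[3]
  }
  ev <- data.frame(time = numeric(), fish_id = integer(), pellet_id = integer())
  if (!is.null(pellets)) {
    pellets <- sink_pellets(pellets, config$dt, config$sink_speed)
    out <- consume_pellets(school, pellets, config, smax,
                           time = time + config$dt)
    school <- out$school; pellets <- out$pellets; ev <- out$events
  }
  list(school = school, pellets = pellets, events = ev)
}
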