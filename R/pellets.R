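#' Pellet mass from sphere geometry
#'
#' A feed pellet is modelled as a sphere of the given diameter at the
#' given density (feed is taken to be neutrally buoyant in the reference
#' scenario, density 1 g/cm^3): mass = (pi/6) d^3 rho.  The default
#' constant used throughout the package is this value rounded to three
#' decimals: 0.065 g for a 5.0 mm pellet.
#'
#' @param diameter Pellet diameter in metres.
#' @param density Pellet density in g/cm^3.
#' @param digits Decimal places for rounding; `NA` returns the exact value.
#' @return Pellet mass in grams.
#' @export
#' @examples
#' pellet_mass_from_geometry(0.005)  # 0.065
pellet_mass_from_geometry <- function(diameter, density = 1.0, digits = 3) {
  stopifnot(diameter >= 0, density > 0)
  d_cm <- diameter * 100
  m <- pi / 6 * d_cm^3 * density
  if (is.na(digits)) m else round(m, digits)
}

#' Create a pellet field
#'
#' @param x,y,z Pellet coordinates in metres.
#' @return A data frame of class `pellet_field` with columns
#'   `id, x, y, z, alive`.
#' @export
pellet_field <- function(x = numeric(), y = numeric(), z = numeric()) {
  n <- length(x)
  y <- rep_len(y, n); z <- rep_len(z, n)
  structure(data.frame(id = seq_len(n), x = x, y = y, z = z,
                       alive = rep(TRUE, n)),
            class = c("pellet_field", "data.frame"))
}

#' Spawn a day's ration of pellets
#'
#' Converts a feed ration (grams) into `floor(ration / pellet_mass)`
#' pellets (never more feed than prescribed) and scatters them i.i.d.
#' uniformly over the method's square footprint at the water surface.
#' Consumes `2 * n` uniform draws from the current RNG stream (x then y).
#'
#' @param ration Feed mass to distribute, grams.
#' @param method A [feeding_method()].
#' @param tank A [tank_geometry()].
#' @param pellet_mass Mass of one pellet, grams.
#' @return A `pellet_field` with all pellets alive at `z = depth`.
#' @export
spawn_pellets <- function(ration, method, tank, pellet_mass = 0.065) {
  stopifnot(ration >= 0, pellet_mass > 0)
  half <- method$square_side / 2
  corner <- sqrt((abs(method$square_center[1]) + half)^2 +
                 (abs(method$square_center[2]) + half)^2)
  if (corner > tank$radius + 1e-12)
    stop("square exceeds tank", call. = FALSE)
  n <- floor(ration / pellet_mass)
  x <- method$square_center[1] + stats::runif(n, -half, half)
  y <- method$square_center[2] + stats::runif(n, -half, half)
  pellet_field(x = x, y = y, z = rep(tank$depth, n))
}

#' Sink pellets by one time step
#'
#' Pellet depth decreases at the fixed sinking speed and is floored at the
#' tank bottom (`z = 0`), where pellets rest and remain edible until the
#' end of the feeding bout.
#'
#' @param pellets A `pellet_field`.
#' @param dt Time step, seconds.
#' @param sink_speed Sinking speed, m/s.
#' @return The updated `pellet_field`.
#' @export
sink_pellets <- function(pellets, dt, sink_speed = 0.025) {
  live <- pellets$alive
  pellets$z[live] <- pmax(0, pellets$z[live] - sink_speed * dt)
  pellets
}

#' Detect fish-pellet contact and consume pellets
#'
#' A live pellet is ingested by fish `i` when the pellet centre lies
#' within `pellet_radius + contact_radius_factor * TL_i` of the fish
#' position and the fish is in feeding mode with intake still below its
#' satiation cap.  Consumed pellets are marked dead immediately and are
#' never re-consumed.  When several eligible fish contact one pellet in
#' the same step, the eater is drawn uniformly at random.  A single fish
#' may take several pellets per step; once its intake reaches the cap it
#' is skipped for the remaining pellets of the step (overshoot is bounded
#' by one pellet mass).
#'
#' This is the reference (pure R) implementation used by the `"r"` engine
#' and in tests; the `"cpp"` engine reimplements it identically.
#'
#' @param school A `fish_school` (see [init_school()]).
#' @param pellets A `pellet_field`.
#' @param config An `experiment_config`.
#' @param smax Per-fish satiation caps, grams (start-of-day mass basis).
#' @param time Simulation time stamped on intake events, seconds.
#' @return A list with elements `school`, `pellets` and `events` (a data
#'   frame `time, fish_id, pellet_id`).
#' @export
consume_pellets <- function(school, pellets, config, smax, time = 0) {
  events <- list()
  live <- which(pellets$alive)
  if (length(live)) {
    contact_r <- config$pellet_diameter / 2 +
      config$contact_radius_factor * school$tl
    feeding <- school$mode == "feeding"
    for (k in live) {
      d2 <- (school$x - pellets$x[k])^2 + (school$y - pellets$y[k])^2 +
        (school$z - pellets$z[k])^2
      cand <- which(feeding & school$intake < smax & d2 <= contact_r^2)
      if (!length(cand)) next
      eater <- if (length(cand) == 1L) cand else
        cand[[floor(stats::runif(1) * length(cand)) + 1L]]
      pellets$alive[k] <- FALSE
      school$intake[eater] <- school$intake[eater] + config$pellet_mass
      school$pellets_eaten[eater] <- school$pellets_eaten[eater] + 1L
      events[[length(events) + 1L]] <-
        data.frame(time = time, fish_id = school$id[eater],
                   pellet_id = pellets$id[k])
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), fish_id = integer(), pellet_id = integer())
  list(school = school, pellets = pellets, events = ev)
}
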