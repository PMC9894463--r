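#' Initialize a school of fish
#'
#' All fish start at the configured initial mass (total length from the
#' allometry), i.i.d. uniform positions inside the tank cylinder, random
#' horizontal headings at the standard-mode cruising speed
#' (`cv_standard * TL`), standard mode, zero intake.  Consumes RNG draws
#' in the documented order: radial positions, angles, depths, headings.
#'
#' @param config An `experiment_config`.
#' @return A data frame of class `fish_school` with columns
#'   `id, x, y, z, vx, vy, vz, mass, tl, mode, intake, pellets_eaten`
#'   (`tl` in metres).
#' @export
init_school <- function(config) {
  n <- config$n_fish
  tl_m <- length_from_mass(config$initial_mass,
                           config$allometry_a, config$allometry_b) / 100
  rmax <- config$tank$radius - CLAMP_EPS
  r <- rmax * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, CLAMP_EPS, config$tank$depth - CLAMP_EPS)
  phi <- stats::runif(n, 0, 2 * pi)
  spd <- config$weights$cv_standard * tl_m
  structure(data.frame(
    id = seq_len(n),
    x = r * cos(th), y = r * sin(th), z = z,
    vx = spd * cos(phi), vy = spd * sin(phi), vz = 0,
    mass = rep(config$initial_mass, n), tl = rep(tl_m, n),
    mode = rep("standard", n), intake = rep(0, n),
    pellets_eaten = rep(0L, n)
  ), class = c("fish_school", "data.frame"))
}

# re-draw positions and headings (daily-randomization variant); speeds use
# each fish's current length
randomize_positions <- function(school, config) {
  n <- nrow(school)
  rmax <- config$tank$radius - CLAMP_EPS
  r <- rmax * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  school$z <- stats::runif(n, CLAMP_EPS, config$tank$depth - CLAMP_EPS)
  phi <- stats::runif(n, 0, 2 * pi)
  school$x <- r * cos(th); school$y <- r * sin(th)
  spd <- config$weights$cv_standard * school$tl
  school$vx <- spd * cos(phi); school$vy <- spd * sin(phi); school$vz <- 0
  school
}

#' Daily feed ration
#'
#' The feed mass distributed per day is a fixed fraction (default 1.86%)
#' of school biomass; the biomass base is either the current total mass
#' (default, compounds with growth) or the initial total mass.
#'
#' @param mass Vector of current body masses, grams (or a `fish_school`).
#' @param config An `experiment_config`.
#' @param initial_biomass Total initial biomass, grams; required only for
#'   `ration_base = "initial"` when `mass` already reflects growth.
#' @return Ration in grams.
#' @export
daily_ration <- function(mass, config, initial_biomass = NULL) {
  if (inherits(mass, "data.frame")) mass <- mass$mass
  base <- switch(config$ration_base,
    current = sum(mass),
    initial = initial_biomass %||% (config$n_fish * config$initial_mass))
  config$ration_fraction * base
}

#' Run a full multi-day feeding and growth experiment
#'
#' Seeds the RNG from `config$rng_seed` and iterates the daily cycle for
#' `config$n_days` days: (optional position re-randomization) -> spawn
#' the day's ration -> feeding bout ([run_feeding_day()]) -> end-of-day
#' growth (`W <- W + FCE * S`) and allometric length update.  When
#' `randomize_daily` is `FALSE` each day starts from the previous day's
#' final kinematic state.
#'
#' `forced_consumption = TRUE` bypasses the behavioral simulation
#' entirely and credits every fish with an equal share `ration / n_fish`
#' each day - the analytic upper bound of mean growth, used as an exact
#' oracle: with FCE = 1 and current-biomass ration the total biomass obeys
#' `B(n) = B(0) (1 + r)^n`.
#'
#' @param config An `experiment_config`.
#' @param forced_consumption Bypass behavior; deterministic equal split.
#' @param engine Passed to [run_feeding_day()].
#' @param progress Emit a message every `progress` days (0 = silent).
#' @return A list of class `feeding_experiment`: `config`, `ledger` (a
#'   data frame with one row per day and fish: `day, fish_id, mass_g,
#'   total_length_cm, intake_g, pellets`; masses are post-growth), `days`
#'   (per-day summary: `day, ration_g, pellets_spawned, pellets_eaten,
#'   completion_time_s`), `school` (final state), `max_speed_excess`.
#' @export
run_experiment <- function(config, forced_consumption = FALSE,
                           engine = c("cpp", "r"), progress = 0) {
  engine <- match.arg(engine)
  validate_config(config)
  set.seed(config$rng_seed)
  school <- init_school(config)
  n <- config$n_fish
  ledgers <- vector("list", config$n_days)
  days <- vector("list", config$n_days)
  max_excess <- 0
  initial_biomass <- sum(school$mass)
  early <- config$early_exit && config$randomize_daily
  for (day in seq_len(config$n_days)) {
    if (config$randomize_daily && day > 1L)
      school <- randomize_positions(school, config)
    ration <- daily_ration(school$mass, config, initial_biomass)
    if (forced_consumption) {
      intake <- rep(ration / n, n)
      pell <- rep(NA_integer_, n)
      days[[day]] <- data.frame(day = day, ration_g = ration,
                                pellets_spawned = NA_integer_,
                                pellets_eaten = NA_integer_,
                                completion_time_s = NA_real_)
    } else {
      res <- run_feeding_day(school, config, day = day,
                             engine = engine, stop_when_consumed = early)
      school <- res$school
      intake <- res$intake
      pell <- res$pellets_per_fish
      max_excess <- max(max_excess, res$max_speed_excess)
      days[[day]] <- data.frame(day = day, ration_g = ration,
                                pellets_spawned = res$pellets_spawned,
                                pellets_eaten = res$pellets_eaten,
                                completion_time_s = res$completion_time)
    }
    school$mass <- daily_growth(school$mass, intake, config$fce)
    school$tl <- length_from_mass(school$mass, config$allometry_a,
                                  config$allometry_b) / 100
    school$intake <- 0
    school$pellets_eaten <- 0L
    school$mode <- "standard"
    ledgers[[day]] <- data.frame(
      day = day, fish_id = school$id, mass_g = school$mass,
      total_length_cm = school$tl * 100, intake_g = intake, pellets = pell)
    if (progress > 0 && day %% progress == 0)
      message(sprintf("day %d/%d: mean mass %.1f g", day, config$n_days,
                      mean(school$mass)))
  }
  structure(list(
    config = config,
    ledger = do.call(rbind, ledgers),
    days = do.call(rbind, days),
    school = school,
    max_speed_excess = max_excess
  ), class = "feeding_experiment")
}

#' @export
print.feeding_experiment <- function(x, ...) {
  m <- x$ledger$mass_g[x$ledger$day == max(x$ledger$day)]
  cat(sprintf(
    "<feeding_experiment> method %s, %d fish, %d days (seed %d)\n",
    x$config$method$name, x$config$n_fish, x$config$n_days,
    x$config$rng_seed))
  cat(sprintf("  final mass: mean %.1f g, sd %.1f g, skewness %.3f\n",
              mean(m), stats::sd(m), skewness(m)))
  invisible(x)
}

#' Derive a replicate sub-seed from a master seed
#'
#' Documented spawning scheme for replicate/method seeds:
#' `(master * 1009 + 101 * method_index + replicate) mod (2^31 - 1)`,
#' avoiding 0.  Deterministic and collision-free for small method and
#' replicate counts.
#'
#' @param master Master seed (integer).
#' @param method_index 1-based index of the feeding method.
#' @param replicate 1-based replicate number.
#' @return An integer seed.
#' @export
derive_seed <- function(master, method_index = 1L, replicate = 1L) {
  s <- (as.double(master) * 1009 + 101 * method_index + replicate) %%
    2147483647
  as.integer(if (s == 0) 1 else s)
}

#' Run the same experiment under several feeding methods
#'
#' One [run_experiment()] per (method, replicate) pair, each with its own
#' sub-seed derived from the master seed via [derive_seed()]; the whole
#' set is deterministic given the master seed.
#'
#' @param base_config An `experiment_config`; its method and seed fields
#'   are overridden per run.
#' @param methods Character vector of method presets or a list of
#'   [feeding_method()] objects.
#' @param replicates Replicates per method.
#' @param master_seed Master seed; default the base config's seed.
#' @param ... Passed on to [run_experiment()].
#' @return A list of `feeding_experiment` objects named
#'   `"<method>.<replicate>"`, with the seed matrix in
#'   `attr(, "seeds")`.
#' @export
run_methods_comparison <- function(base_config, methods = c("A", "B", "C"),
                                   replicates = 1L, master_seed = NULL,
                                   ...) {
  master_seed <- master_seed %||% base_config$rng_seed
  out <- list()
  seeds <- matrix(NA_integer_, length(methods), replicates)
  for (mi in seq_along(methods)) {
    m <- methods[[mi]]
    if (is.character(m)) m <- feeding_method(m)
    for (r in seq_len(replicates)) {
      cfg <- base_config
      cfg$method <- m
      cfg$rng_seed <- derive_seed(master_seed, mi, r)
      seeds[mi, r] <- cfg$rng_seed
      out[[paste0(m$name, ".", r)]] <- run_experiment(cfg, ...)
    }
  }
  attr(out, "seeds") <- seeds
  out
}
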