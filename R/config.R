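#' @importFrom Rcpp evalCpp
#' @useDynLib schoolfeed, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Behavioral rule weights and speed-cap coefficients
#'
#' The schooling kernel steers each fish by six weighted rules: separation
#' (`w1`), cohesion (`w2`), alignment (`w3`), boundary avoidance (`w4`),
#' feed attraction (`w5`, mode-dependent) and random movement (`w6`).  The
#' speed cap is `Cv * TL` (total length in metres, speed in m/s) with a
#' mode-dependent coefficient: `cv_standard` for routine cruising and
#' `cv_feeding` for burst swimming towards feed.
#'
#' @param w1,w2,w3,w4,w6 Non-negative rule weights (force units).
#' @param w5_standard,w5_feeding Feed-attraction weight per behavioral mode;
#'   satiated (standard-mode) fish ignore feed.
#' @param cv_standard,cv_feeding Speed-cap coefficient (1/s, multiplies
#'   total length); `cv_feeding >= cv_standard > 0`.
#' @return A validated list of class `behavior_weights`.
#' @export
behavior_weights <- function(w1 = 0.6, w2 = 0.4, w3 = 0.4, w4 = 1.0,
                             w5_standard = 0.0, w5_feeding = 3.0, w6 = 0.2,
                             cv_standard = 1.5, cv_feeding = 7.0) {
  w <- list(w1 = w1, w2 = w2, w3 = w3, w4 = w4,
            w5_standard = w5_standard, w5_feeding = w5_feeding, w6 = w6,
            cv_standard = cv_standard, cv_feeding = cv_feeding)
  for (nm in names(w)) {
    if (!is.numeric(w[[nm]]) || length(w[[nm]]) != 1L || !is.finite(w[[nm]]))
      stop("behavior weight '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (any(unlist(w[c("w1", "w2", "w3", "w4", "w5_standard", "w5_feeding", "w6")]) < 0))
    stop("behavior weights w1..w6 must be >= 0", call. = FALSE)
  if (!(w$cv_standard > 0)) stop("cv_standard must be > 0", call. = FALSE)
  if (w$cv_feeding < w$cv_standard)
    stop("cv_feeding must be >= cv_standard", call. = FALSE)
  structure(w, class = "behavior_weights")
}

#' Cylindrical tank geometry
#'
#' The simulated domain is a vertical cylinder: the tank axis is the
#' horizontal origin, `z = 0` is the bottom and the water surface sits at
#' `z = depth`.
#'
#' @param radius Tank radius in metres (default 1.5, a 3.0 m diameter tank).
#' @param depth Water depth in metres.
#' @return A list of class `tank_geometry`.
#' @export
tank_geometry <- function(radius = 1.5, depth = 1.5) {
  if (!is.numeric(radius) || length(radius) != 1L || !(radius > 0))
    stop("tank radius must be > 0", call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || !(depth > 0))
    stop("tank depth must be > 0", call. = FALSE)
  structure(list(radius = radius, depth = depth), class = "tank_geometry")
}

#' Square feed-broadcast footprint
#'
#' Feed pellets are released at the surface, uniformly over a square
#' centred (by default) on the tank axis.  Three named presets are built
#' in: methods `"A"`, `"B"` and `"C"` with side lengths 1.5, 1.0 and
#' 0.5 m, spanning wide to narrow feed broadcasting.
#'
#' @param name Method label: `"A"`, `"B"`, `"C"`, or any label when
#'   `square_side` is given explicitly.
#' @param square_side Side length of the square in metres; defaults to the
#'   preset value for named methods.
#' @param square_center Horizontal centre `c(x, y)` in metres.
#' @return A list of class `feeding_method`.
#' @export
#' @examples
#' feeding_method("C")$square_side  # 0.5
feeding_method <- function(name = "A", square_side = NULL,
                           square_center = c(0, 0)) {
  presets <- c(A = 1.5, B = 1.0, C = 0.5)
  if (is.null(square_side)) {
    if (!name %in% names(presets))
      stop("unknown feeding method '", name,
           "' (expected A, B or C, or an explicit square_side)", call. = FALSE)
    square_side <- unname(presets[[name]])
  }
  if (!is.numeric(square_side) || length(square_side) != 1L || !(square_side > 0))
    stop("square_side must be > 0", call. = FALSE)
  if (length(square_center) != 2L || !all(is.finite(square_center)))
    stop("square_center must be a finite (x, y) pair", call. = FALSE)
  structure(list(name = as.character(name), square_side = square_side,
                 square_center = as.numeric(square_center)),
            class = "feeding_method")
}

#' Full experiment configuration
#'
#' Assembles and validates every parameter of a feeding/growth experiment.
#' The defaults reproduce the reference scenario: 100 rainbow trout of
#' 38.53 g in a 3.0 m x 1.5 m tank, fed once daily at 1.86% of school
#' biomass with 5 mm neutrally buoyant pellets (0.065 g) sinking at
#' 0.025 m/s, a 1000 s feeding bout at time step 0.025 s, satiation at 4%
#' of body mass, FCE 1, allometry `W = 0.0209 TL^2.843` (g, cm), over 90
#' days.
#'
#' @param n_fish Number of individuals.
#' @param initial_mass Initial body mass of every fish, grams.
#' @param ration_fraction Daily feed ration as a fraction of school biomass.
#' @param ration_base `"current"` (today's biomass) or `"initial"`.
#' @param fce Feed conversion efficiency (mass gain per mass ingested).
#' @param smax_fraction Daily satiation cap as a fraction of body mass.
#' @param pellet_diameter Pellet diameter, metres.
#' @param pellet_density Pellet density, g/cm^3 (water = 1).
#' @param pellet_mass Pellet mass in grams; default derived from geometry
#'   and rounded to 3 decimals (see [pellet_mass_from_geometry()]).
#' @param sink_speed Pellet sinking speed, m/s.
#' @param dt Integration time step, seconds.
#' @param feeding_duration Length of the daily feeding bout, seconds.
#' @param n_days Number of simulated days.
#' @param randomize_daily Re-randomize fish positions before each day's
#'   feeding (otherwise each day starts from the previous day's final
#'   kinematic state).
#' @param early_exit End a day's inner loop once all pellets are consumed;
#'   only honored together with `randomize_daily = TRUE`, where final
#'   positions are irrelevant.
#' @param rng_seed Master seed for the run.
#' @param method A [feeding_method()] or a preset name.
#' @param tank A [tank_geometry()].
#' @param weights A [behavior_weights()].
#' @param allometry_a,allometry_b Length-mass allometry `W = a TL^b`
#'   with `W` in grams and `TL` in centimetres.
#' @param fov_radius_factor Field-of-view radius as a multiple of total
#'   length (sphere of radius `factor * TL`).
#' @param dead_zone_half_angle Rear blind-cone half angle, degrees.
#' @param contact_radius_factor Feed-capture ("mouth") radius as a multiple
#'   of total length, added to the pellet radius; the calibration knob of
#'   the contact model.  The default 0.08 (a strike sphere of about 1.4 cm
#'   for a 14 cm fish) keeps day-1 feeding completion within the reported
#'   bounds while reproducing the reported magnitude of between-individual
#'   growth variance; see the methods vignette.
#' @param force_scale Divisor converting body mass in grams to the inertial
#'   mass used in the force balance; 1000 treats rule weights as
#'   newton-scale forces acting on a mass in kilograms.
#' @param isotropic_random If `TRUE`, draw the random-movement direction
#'   uniformly on the sphere instead of the literal normalized-cube scheme
#'   (which slightly over-represents corner directions).
#' @return A validated list of class `experiment_config`.
#' @seealso [load_config()], [run_experiment()]
#' @export
experiment_config <- function(n_fish = 100L,
                              initial_mass = 38.53,
                              ration_fraction = 0.0186,
                              ration_base = c("current", "initial"),
                              fce = 1.0,
                              smax_fraction = 0.04,
                              pellet_diameter = 0.005,
                              pellet_density = 1.0,
                              pellet_mass = NULL,
                              sink_speed = 0.025,
                              dt = 0.025,
                              feeding_duration = 1000,
                              n_days = 90L,
                              randomize_daily = FALSE,
                              early_exit = FALSE,
                              rng_seed = 1L,
                              method = feeding_method("A"),
                              tank = tank_geometry(),
                              weights = behavior_weights(),
                              allometry_a = 0.0209,
                              allometry_b = 2.843,
                              fov_radius_factor = 2,
                              dead_zone_half_angle = 30,
                              contact_radius_factor = 0.08,
                              force_scale = 1000,
                              isotropic_random = FALSE) {
  ration_base <- match.arg(ration_base)
  if (is.character(method)) method <- feeding_method(method)
  if (!inherits(method, "feeding_method")) method <- do.call(feeding_method, method)
  if (!inherits(tank, "tank_geometry")) tank <- do.call(tank_geometry, tank)
  if (!inherits(weights, "behavior_weights")) weights <- do.call(behavior_weights, weights)
  if (is.null(pellet_mass))
    pellet_mass <- pellet_mass_from_geometry(pellet_diameter, pellet_density)
  cfg <- structure(list(
    n_fish = as.integer(n_fish), initial_mass = initial_mass,
    ration_fraction = ration_fraction, ration_base = ration_base,
    fce = fce, smax_fraction = smax_fraction,
    pellet_diameter = pellet_diameter, pellet_density = pellet_density,
    pellet_mass = pellet_mass, sink_speed = sink_speed,
    dt = dt, feeding_duration = feeding_duration,
    n_days = as.integer(n_days), randomize_daily = isTRUE(randomize_daily),
    early_exit = isTRUE(early_exit), rng_seed = as.integer(rng_seed),
    method = method, tank = tank, weights = weights,
    allometry_a = allometry_a, allometry_b = allometry_b,
    fov_radius_factor = fov_radius_factor,
    dead_zone_half_angle = dead_zone_half_angle,
    contact_radius_factor = contact_radius_factor,
    force_scale = force_scale,
    isotropic_random = isTRUE(isotropic_random)
  ), class = "experiment_config")
  validate_config(cfg)
}

#' Validate an experiment configuration
#'
#' Checks every structural invariant (positive geometry, fractions in
#' (0, 1), positive time step, feed square inscribed in the tank circle,
#' ...) and returns the configuration invisibly unchanged.  Errors name the
#' offending field.
#'
#' @param cfg An `experiment_config`.
#' @return `cfg`, invisibly validated.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$n_fish >= 1L, "n_fish must be >= 1")
  chk(cfg$initial_mass > 0, "initial_mass must be > 0")
  chk(cfg$ration_fraction > 0 && cfg$ration_fraction < 1,
      "ration_fraction must be in (0, 1)")
  chk(cfg$smax_fraction > 0 && cfg$smax_fraction < 1,
      "smax_fraction must be in (0, 1)")
  chk(cfg$fce > 0, "fce must be > 0")
  chk(cfg$pellet_mass > 0, "pellet_mass must be > 0")
  chk(cfg$pellet_diameter > 0, "pellet_diameter must be > 0")
  chk(cfg$sink_speed >= 0, "sink_speed must be >= 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$feeding_duration >= cfg$dt, "feeding_duration must cover >= 1 step")
  chk(cfg$n_days >= 1L, "n_days must be >= 1")
  chk(cfg$allometry_a > 0 && cfg$allometry_b > 0,
      "allometry coefficients must be > 0")
  chk(cfg$fov_radius_factor > 0, "fov_radius_factor must be > 0")
  chk(cfg$dead_zone_half_angle >= 0 && cfg$dead_zone_half_angle < 180,
      "dead_zone_half_angle must be in [0, 180)")
  chk(cfg$contact_radius_factor > 0, "contact_radius_factor must be > 0")
  chk(cfg$force_scale > 0, "force_scale must be > 0")
  # feed square must be fully inside the tank circle
  half <- cfg$method$square_side / 2
  ctr <- cfg$method$square_center
  corner <- max(sqrt((abs(ctr[1]) + half)^2 + (abs(ctr[2]) + half)^2))
  if (corner > cfg$tank$radius + 1e-12)
    stop("feeding_method: square exceeds tank (corner at ",
         signif(corner, 4), " m from axis, tank radius ",
         cfg$tank$radius, " m)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  %d fish, %.4g g initial mass, %d days, seed %d\n",
              x$n_fish, x$initial_mass, x$n_days, x$rng_seed))
  cat(sprintf("  tank: radius %.3g m, depth %.3g m\n",
              x$tank$radius, x$tank$depth))
  cat(sprintf("  feeding: method %s (square side %.3g m), ration %.4g%% of %s biomass\n",
              x$method$name, x$method$square_side,
              100 * x$ration_fraction, x$ration_base))
  cat(sprintf("  pellets: %.3g g, sink %.3g m/s; bout %.4g s at dt %.3g s\n",
              x$pellet_mass, x$sink_speed, x$feeding_duration, x$dt))
  cat(sprintf("  randomize_daily: %s\n", x$randomize_daily))
  invisible(x)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$method <- unclass(out$method)
  out$tank <- unclass(out$tank)
  out$weights <- unclass(out$weights)
  out
}

#' Load a configuration from JSON
#'
#' Reads a (possibly partial) JSON configuration file and merges it over
#' the package defaults; explicit `overrides` take precedence over file
#' values.  Nested sections `tank`, `weights` and `method` are merged
#' field-wise.
#'
#' @param source Path to a JSON file, or a named list of fields (use
#'   `NULL`/empty list for pure defaults).
#' @param overrides Named list applied after the file values.
#' @return A validated `experiment_config`.
#' @seealso [write_config()]
#' @export
load_config <- function(source = NULL, overrides = list()) {
  vals <- list()
  if (is.character(source)) {
    if (!file.exists(source)) stop("config file not found: ", source, call. = FALSE)
    vals <- jsonlite::read_json(source, simplifyVector = TRUE)
  } else if (is.list(source)) {
    vals <- source
  } else if (!is.null(source)) {
    stop("source must be a file path, a list, or NULL", call. = FALSE)
  }
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(experiment_config))
  known <- setdiff(known, "pellet_mass")  # recomputed unless given
  unknown <- setdiff(names(vals), c(known, "pellet_mass"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in c("tank", "weights", "method"))
    if (!is.null(vals[[sec]])) vals[[sec]] <- as.list(vals[[sec]])
  do.call(experiment_config, vals)
}

#' Write a configuration to JSON
#'
#' Serialization is lossless: `load_config(write_config(cfg, path))`
#' reproduces `cfg` exactly (full-precision numbers).
#'
#' @param cfg An `experiment_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  # digits = I(17): decimal round trip is exact for IEEE doubles
  jsonlite::write_json(config_to_list(cfg), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
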