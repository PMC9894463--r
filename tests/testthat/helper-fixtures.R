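# shared fixture builders: every fixture is generated in code at test time

# a school data frame from explicit state vectors
make_school <- function(x, y, z, vx = 0, vy = 0, vz = 0,
                        mass = 38.53, tl = NULL) {
  n <- length(x)
  if (is.null(tl)) tl <- length_from_mass(mass) / 100
  structure(data.frame(
    id = seq_len(n), x = x, y = y, z = z,
    vx = rep_len(vx, n), vy = rep_len(vy, n), vz = rep_len(vz, n),
    mass = rep_len(mass, n), tl = rep_len(tl, n),
    mode = rep("standard", n), intake = rep(0, n),
    pellets_eaten = rep(0L, n)
  ), class = c("fish_school", "data.frame"))
}

# small, fast configuration for micro scenarios
micro_config <- function(n_fish = 2L, feeding_duration = 1, ...) {
  experiment_config(n_fish = n_fish, feeding_duration = feeding_duration,
                    n_days = 1L, ...)
}

# one C++ engine step driven with an explicit random-force matrix
cpp_steps <- function(school, pellets, config, n_steps, f6 = NULL,
                      smax = smax_intake(school$mass, config$smax_fraction)) {
  if (is.null(pellets)) pellets <- pellet_field()
  schoolfeed:::run_feeding_day_cpp(
    pos = cbind(school$x, school$y, school$z),
    vel = cbind(school$vx, school$vy, school$vz),
    mass = school$mass, tl = school$tl, smax = smax,
    pellet_xyz = cbind(pellets$x, pellets$y, pellets$z),
    pellet_alive = pellets$alive,
    par = schoolfeed:::engine_params(config),
    n_steps = as.integer(n_steps), stop_when_consumed = FALSE,
    record_events = TRUE, f6 = f6)
}

# random but physically valid state for oracle comparisons
random_state <- function(n, config, seed) {
  set.seed(seed)
  r <- (config$tank$radius - 0.05) * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  mass <- runif(n, 20, 200)
  tl <- length_from_mass(mass) / 100
  sc <- make_school(x = r * cos(th), y = r * sin(th),
                    z = runif(n, 0.05, config$tank$depth - 0.05),
                    vx = runif(n, -0.2, 0.2), vy = runif(n, -0.2, 0.2),
                    vz = runif(n, -0.05, 0.05), mass = mass, tl = tl)
  sc
}
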