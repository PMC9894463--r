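test_that("behavioral mode follows appetite and feed presence", {
  expect_identical(select_mode(0, 1.54, TRUE), "feeding")
  expect_identical(select_mode(1.60, 1.54, TRUE), "standard")
  expect_identical(select_mode(1.54, 1.54, TRUE), "standard")  # cap reached
  expect_identical(select_mode(0, 1.54, FALSE), "standard")
  expect_identical(select_mode(c(0, 2), c(1.5, 1.5), TRUE),
                   c("feeding", "standard"))
})

test_that("a day with no feed leaves the school unfed in standard mode", {
  cfg <- micro_config(n_fish = 3L, feeding_duration = 2)
  set.seed(2)
  school <- init_school(cfg)
  res <- run_feeding_day(school, cfg, pellets = pellet_field())
  expect_equal(res$intake, rep(0, 3))
  expect_true(is.na(res$completion_time))
  expect_true(all(res$school$mode == "standard"))
  expect_identical(res$pellets_spawned, 0L)
})

test_that("a single pellet directly ahead is taken at the first step", {
  cfg <- micro_config(n_fish = 1L, feeding_duration = 1)
  sc <- make_school(x = 0, y = 0, z = 0.75)
  pel <- pellet_field(x = 0.02, y = 0, z = 0.75)
  for (engine in c("cpp", "r")) {
    set.seed(3)
    res <- run_feeding_day(sc, cfg, pellets = pel, engine = engine,
                           record_events = TRUE)
    expect_equal(res$intake, 0.065, label = engine)
    expect_equal(res$completion_time, cfg$dt, label = engine)
    expect_equal(res$events$time, cfg$dt)
  }
})

test_that("compiled and reference engines agree on random states", {
  cfg <- experiment_config(n_fish = 10L)
  for (k in 1:20) {
    sc <- random_state(10, cfg, seed = 500 + k)
    set.seed(600 + k)
    pel <- pellet_field(x = runif(6, -0.7, 0.7), y = runif(6, -0.7, 0.7),
                        z = runif(6, 0.3, 1.5))
    f6 <- matrix(runif(30, -0.2, 0.2), 10, 3)
    smax <- smax_intake(sc$mass)
    # identical RNG state for both engines so contested-pellet tie-breaks
    # (rare but possible in random states) resolve identically
    set.seed(700 + k)
    res <- cpp_steps(sc, pel, cfg, n_steps = 1L, f6 = f6, smax = smax)
    set.seed(700 + k)
    st <- step_school(sc, pel, cfg, smax, time = 0, f6 = f6)
    expect_equal(res$pos, unname(cbind(st$school$x, st$school$y, st$school$z)),
                 tolerance = 1e-12)
    expect_equal(res$vel,
                 unname(cbind(st$school$vx, st$school$vy, st$school$vz)),
                 tolerance = 1e-12)
    expect_equal(res$intake, st$school$intake)
    expect_identical(res$pellet_alive, st$pellets$alive)
  }
})

test_that("engines track each other over a multi-step trajectory", {
  cfg <- experiment_config(n_fish = 8L)
  sc <- random_state(8, cfg, seed = 42)
  set.seed(43)
  pel <- pellet_field(x = runif(10, -0.5, 0.5), y = runif(10, -0.5, 0.5),
                      z = runif(10, 0.5, 1.5))
  f6 <- matrix(runif(24, -0.2, 0.2), 8, 3)
  smax <- smax_intake(sc$mass)
  set.seed(44)
  res <- cpp_steps(sc, pel, cfg, n_steps = 60L, f6 = f6, smax = smax)
  set.seed(44)
  sr <- sc; pr <- pel
  for (s in 1:60) {
    st <- step_school(sr, pr, cfg, smax, time = (s - 1) * cfg$dt, f6 = f6)
    sr <- st$school; pr <- st$pellets
  }
  expect_equal(res$pos, unname(cbind(sr$x, sr$y, sr$z)), tolerance = 1e-9)
  expect_equal(res$intake, sr$intake)
  expect_identical(res$pellet_alive, pr$alive)
  expect_equal(res$pellet_z[res$pellet_alive], pr$z[pr$alive])
})

test_that("per-fish intake never exceeds the cap plus one pellet", {
  cfg <- experiment_config(n_fish = 6L, feeding_duration = 60,
                           rng_seed = 9L)
  set.seed(9)
  school <- init_school(cfg)
  # flood the tank with feed so every fish can reach its cap
  set.seed(10)
  pel <- spawn_pellets(60, cfg$method, cfg$tank, cfg$pellet_mass)
  res <- run_feeding_day(school, cfg, pellets = pel)
  smax <- smax_intake(school$mass)
  expect_true(all(res$intake <= smax + cfg$pellet_mass + 1e-12))
  expect_gt(max(res$intake), 0)
  expect_equal(res$max_speed_excess, 0, tolerance = 1e-9)
})

test_that("deterministic kernel preserves mirror symmetry (w6 = 0)", {
  cfg <- experiment_config(
    n_fish = 2L,
    weights = behavior_weights(w6 = 0))
  sc <- make_school(x = c(0.1, -0.1), y = c(0.1, 0.1), z = 0.75,
                    vx = c(-0.1, 0.1), vy = c(0.05, 0.05))
  res <- cpp_steps(sc, NULL, cfg, n_steps = 200L)
  # trajectories mirror through the x = 0 plane
  expect_equal(res$pos[1, 1], -res$pos[2, 1], tolerance = 1e-12)
  expect_equal(res$pos[1, 2], res$pos[2, 2], tolerance = 1e-12)
  expect_equal(res$pos[1, 3], res$pos[2, 3], tolerance = 1e-12)
  expect_equal(res$vel[1, 1], -res$vel[2, 1], tolerance = 1e-12)
  expect_equal(res$vel[1, 2], res$vel[2, 2], tolerance = 1e-12)
})

test_that("early termination preserves the completion time", {
  cfg <- micro_config(n_fish = 5L, feeding_duration = 120)
  set.seed(6)
  school <- init_school(cfg)
  set.seed(7)
  pel <- spawn_pellets(0.065 * 20, cfg$method, cfg$tank, cfg$pellet_mass)
  set.seed(8)
  full <- run_feeding_day(school, cfg, pellets = pel)
  set.seed(8)
  fast <- run_feeding_day(school, cfg, pellets = pel, stop_when_consumed = TRUE)
  expect_equal(fast$completion_time, full$completion_time)
  expect_lte(fast$steps_run, full$steps_run)
})
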