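test_that("pellet mass follows the sphere closed form", {
  expect_identical(pellet_mass_from_geometry(0.005, 1.0), 0.065)
  expect_identical(pellet_mass_from_geometry(0), 0)
  expect_identical(pellet_mass_from_geometry(0.010, 1.0), 0.524)
  # exact value before rounding: (pi/6) * 0.5^3 cm^3
  expect_equal(pellet_mass_from_geometry(0.005, 1.0, digits = NA),
               pi / 6 * 0.125)
})

test_that("spawning floors the pellet count and fills the square uniformly", {
  tank <- tank_geometry()
  set.seed(4)
  # day-1 reference ration: 1.86% of 100 x 38.53 g = 71.6658 g -> 1102 pellets
  p <- spawn_pellets(71.6658, feeding_method("A"), tank, 0.065)
  expect_identical(nrow(p), 1102L)
  expect_true(all(p$alive))
  expect_true(all(p$z == tank$depth))
  expect_true(all(abs(p$x) <= 0.75) && all(abs(p$y) <= 0.75))
  # one pellet mass spawns exactly one pellet inside the footprint
  p1 <- spawn_pellets(0.065, feeding_method("C"), tank, 0.065)
  expect_identical(nrow(p1), 1L)
  expect_true(abs(p1$x) <= 0.25 && abs(p1$y) <= 0.25)
  # marginals uniform on [-0.25, 0.25] for the narrow square
  set.seed(14)
  pc <- spawn_pellets(0.065 * 1e4, feeding_method("C"), tank, 0.065)
  expect_gt(stats::ks.test(pc$x, "punif", -0.25, 0.25)$p.value, 1e-4)
  expect_gt(stats::ks.test(pc$y, "punif", -0.25, 0.25)$p.value, 1e-4)
  expect_error(spawn_pellets(1, feeding_method("big", square_side = 4), tank),
               "square exceeds tank")
})

test_that("pellets sink at fixed speed and rest on the bottom", {
  p <- pellet_field(x = 0, y = 0, z = 1.5)
  # one step: dz = 0.025 m/s * 0.025 s
  p1 <- sink_pellets(p, dt = 0.025)
  expect_equal(p1$z, 1.5 - 0.000625)
  # surface to bottom takes 60 s of sinking
  for (k in 1:2400) p <- sink_pellets(p, dt = 0.025)
  expect_equal(p$z, 0)
  expect_equal(sink_pellets(p, dt = 0.025)$z, 0)   # stays on the bottom
})

test_that("contact consumption obeys mode, cap and single-consumption", {
  cfg <- micro_config()
  # feeding fish coincident with a live pellet eats it
  sc <- make_school(x = 0, y = 0, z = 0.75)
  sc$mode <- "feeding"
  pel <- pellet_field(x = 0, y = 0, z = 0.75)
  out <- consume_pellets(sc, pel, cfg, smax = 1.5412, time = 0.025)
  expect_identical(nrow(out$events), 1L)
  expect_false(out$pellets$alive)
  expect_equal(out$school$intake, 0.065)
  expect_identical(out$school$pellets_eaten, 1L)
  # a second pass cannot re-consume the dead pellet
  out2 <- consume_pellets(out$school, out$pellets, cfg, smax = 1.5412)
  expect_identical(nrow(out2$events), 0L)
  expect_equal(out2$school$intake, 0.065)
  # standard-mode fish swims past the feed
  sc2 <- make_school(x = 0, y = 0, z = 0.75)   # mode "standard"
  out3 <- consume_pellets(sc2, pellet_field(0, 0, 0.75), cfg, smax = 1.5412)
  expect_identical(nrow(out3$events), 0L)
  expect_true(out3$pellets$alive)
  # a fish at its cap is ineligible
  sc3 <- make_school(x = 0, y = 0, z = 0.75)
  sc3$mode <- "feeding"; sc3$intake <- 1.56
  out4 <- consume_pellets(sc3, pellet_field(0, 0, 0.75), cfg, smax = 1.5412)
  expect_identical(nrow(out4$events), 0L)
})

test_that("contested pellets are assigned uniformly at random", {
  cfg <- micro_config()
  sc <- make_school(x = c(0.001, -0.001), y = 0, z = 0.75)
  sc$mode <- "feeding"
  pel <- pellet_field(x = 0, y = 0, z = 0.75)
  set.seed(8)
  wins <- integer(2)
  n_trials <- 4000L
  for (k in seq_len(n_trials)) {
    out <- consume_pellets(sc, pel, cfg, smax = c(1.54, 1.54))
    wins[out$events$fish_id] <- wins[out$events$fish_id] + 1L
  }
  expect_identical(sum(wins), n_trials)
  # each fish wins ~50%; 4000 trials give a ~1.6% two-sigma band
  expect_lt(abs(wins[1] / n_trials - 0.5), 0.03)
})

test_that("daily mass bookkeeping is exact", {
  cfg <- micro_config(n_fish = 4L, feeding_duration = 5)
  set.seed(12)
  school <- init_school(cfg)
  pel <- spawn_pellets(0.065 * 40, cfg$method, cfg$tank, cfg$pellet_mass)
  res <- run_feeding_day(school, cfg, pellets = pel, engine = "r",
                         record_events = TRUE)
  # counts are exact: one event per eaten pellet, never more than spawned
  expect_identical(nrow(res$events), res$pellets_eaten)
  expect_lte(res$pellets_eaten, res$pellets_spawned)
  expect_equal(sum(res$intake), res$pellets_eaten * 0.065)
  # no pellet id appears twice in the event log
  expect_false(anyDuplicated(res$events$pellet_id) > 0)
})
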