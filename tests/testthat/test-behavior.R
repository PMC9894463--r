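cfg0 <- experiment_config()
TL <- length_from_mass(38.53) / 100  # ~0.1408 m

test_that("field of view: sphere radius 2 TL minus the rear dead cone", {
  # focal at tank centre moving +x; other fish placed around it
  mid <- cfg0$tank$depth / 2
  sc <- make_school(x = c(0, 1.9 * TL, 2.1 * TL, -1.0 * TL),
                    y = 0, z = mid, vx = c(0.2, 0, 0, 0))
  p <- perceive(sc, 1, cfg0)
  expect_true(2L %in% p$neighbor_ids)       # ahead at 1.9 TL: in view
  expect_false(3L %in% p$neighbor_ids)      # ahead at 2.1 TL: outside sphere
  expect_false(4L %in% p$neighbor_ids)      # directly behind: dead cone
  expect_identical(p$nearest_neighbor_id, 2L)

  # brute-force the 30-degree half-angle over a grid of rear directions
  for (ang_deg in c(5, 15, 29, 31, 45, 90, 135)) {
    a <- ang_deg * pi / 180
    d <- 1.0 * TL
    sc2 <- make_school(x = c(0, -d * cos(a)), y = c(0, d * sin(a)), z = mid,
                       vx = c(0.2, 0))
    p2 <- perceive(sc2, 1, cfg0)
    expect_identical(2L %in% p2$neighbor_ids, ang_deg > 30,
                     label = paste("angle", ang_deg))
  }
  # stationary focal fish has no dead cone
  sc3 <- make_school(x = c(0, -1.0 * TL), y = 0, z = mid, vx = 0)
  expect_true(2L %in% perceive(sc3, 1, cfg0)$neighbor_ids)
})

test_that("separation repels from the nearest in-view individual", {
  mid <- 0.75
  sc <- make_school(x = c(0, 1), y = 0, z = mid, tl = 1)  # huge TL: all in view
  p <- perceive(sc, 1, cfg0)
  expect_equal(separation_force(sc, 1, p, 0.6), c(-0.6, 0, 0))
  # no neighbor in view -> zero
  sc2 <- make_school(x = c(0, 10 * TL), y = 0, z = mid)
  expect_equal(separation_force(sc2, 1, perceive(sc2, 1, cfg0), 0.6),
               c(0, 0, 0))
  # only the nearest of two neighbors matters
  sc3 <- make_school(x = c(0, 0.1, -0.2), y = 0, z = mid, tl = 1)
  p3 <- perceive(sc3, 1, cfg0)
  expect_identical(p3$nearest_neighbor_id, 2L)
  expect_equal(separation_force(sc3, 1, p3, 0.6), c(-0.6, 0, 0))
})

test_that("cohesion attracts to the in-view centroid", {
  mid <- 0.75
  sc <- make_school(x = c(0, 1, -1), y = c(1, 0, 0), z = mid, tl = 1)
  p <- perceive(sc, 1, cfg0)
  expect_equal(cohesion_force(sc, 1, p, 0.4), c(0, -0.4, 0))
  # single neighbor: direction identical to unit(xj - xi)
  sc2 <- make_school(x = c(0, 0.3), y = c(0, 0.4), z = mid, tl = 1)
  f <- cohesion_force(sc2, 1, perceive(sc2, 1, cfg0), 0.4)
  expect_equal(f, 0.4 * c(0.3, 0.4, 0) / 0.5)
  # 5 random neighbors: matches brute-force mean-then-normalize
  set.seed(9)
  xs <- runif(6, -0.3, 0.3); ys <- runif(6, -0.3, 0.3)
  zs <- runif(6, 0.6, 0.9)
  sc3 <- make_school(x = xs, y = ys, z = zs, tl = 1)
  p3 <- perceive(sc3, 1, cfg0)
  ctr <- c(mean(xs[-1]), mean(ys[-1]), mean(zs[-1]))
  d <- ctr - c(xs[1], ys[1], zs[1])
  expect_equal(cohesion_force(sc3, 1, p3, 0.4), 0.4 * d / sqrt(sum(d^2)))
})

test_that("alignment steers towards the in-view mean velocity", {
  mid <- 0.75
  sc <- make_school(x = c(0, 0.1), y = 0, z = mid, vx = c(0.1, 0.1), tl = 1)
  expect_equal(alignment_force(sc, 1, perceive(sc, 1, cfg0), 0.4), c(0, 0, 0))
  sc2 <- make_school(x = c(0, 0.1), y = 0, z = mid, vx = c(0, 0.2), tl = 1)
  expect_equal(alignment_force(sc2, 1, perceive(sc2, 1, cfg0), 0.4),
               c(0.4, 0, 0))
  set.seed(10)
  sc3 <- make_school(x = runif(4, -0.2, 0.2), y = runif(4, -0.2, 0.2),
                     z = 0.75, vx = runif(4, -0.3, 0.3),
                     vy = runif(4, -0.3, 0.3), vz = runif(4, -0.1, 0.1),
                     tl = 1)
  p3 <- perceive(sc3, 1, cfg0)
  ids <- p3$neighbor_ids   # the moving focal fish has a rear dead cone
  expect_gt(length(ids), 0L)
  vbar <- c(mean(sc3$vx[ids]), mean(sc3$vy[ids]), mean(sc3$vz[ids]))
  d <- vbar - c(sc3$vx[1], sc3$vy[1], sc3$vz[1])
  expect_equal(alignment_force(sc3, 1, p3, 0.4), 0.4 * d / sqrt(sum(d^2)))
})

test_that("boundary avoidance repels from the nearest in-view boundary", {
  # near the wall: inward radial force of magnitude w4
  sc <- make_school(x = 1.45, y = 0, z = 0.75)
  p <- perceive(sc, 1, cfg0)
  expect_equal(p$nearest_boundary_point, c(1.5, 0, 0.75))
  expect_equal(boundary_force(sc, 1, p, 1.0, cfg0$tank), c(-1, 0, 0))
  # tank centre, mid-depth: every boundary farther than 2 TL -> zero
  sc2 <- make_school(x = 0, y = 0, z = 0.75)
  p2 <- perceive(sc2, 1, cfg0)
  expect_null(p2$nearest_boundary_point)
  expect_equal(boundary_force(sc2, 1, p2, 1.0, cfg0$tank), c(0, 0, 0))
  # bottom corner: nearest of the three candidates by brute force
  for (pos in list(c(1.48, 0, 0.10), c(1.40, 0.2, 0.05), c(0.5, 0.5, 0.02))) {
    sc3 <- make_school(x = pos[1], y = pos[2], z = pos[3])
    p3 <- perceive(sc3, 1, cfg0)
    r <- sqrt(pos[1]^2 + pos[2]^2)
    cand <- list(wall = c(pos[1] * 1.5 / r, pos[2] * 1.5 / r, pos[3]),
                 bottom = c(pos[1], pos[2], 0),
                 surface = c(pos[1], pos[2], 1.5))
    d <- vapply(cand, function(b) sqrt(sum((b - pos)^2)), 0)
    expect_equal(p3$nearest_boundary_point, cand[[which.min(d)]])
  }
})

test_that("feed attraction targets the nearest pellet regardless of view", {
  sc <- make_school(x = 0, y = 0, z = 0.75)
  sc$mode <- "feeding"
  # nearest pellet far outside the 2 TL sphere is still detected
  pel <- pellet_field(x = c(1.2, 0.3), y = 0, z = 0.75)
  p <- perceive(sc, 1, cfg0, pel)
  expect_equal(p$nearest_pellet_position, c(0.3, 0, 0.75))
  expect_equal(feed_force(sc, 1, p, 3.0), c(3, 0, 0))
  # standard-mode weight is zero
  expect_equal(feed_force(sc, 1, p, 0.0), c(0, 0, 0))
  # pellet overhead
  pel2 <- pellet_field(x = 0, y = 0, z = 1.5)
  p2 <- perceive(sc, 1, cfg0, pel2)
  expect_equal(feed_force(sc, 1, p2, 3.0), c(0, 0, 3))
})

test_that("random movement has fixed magnitude and a seeded stream", {
  set.seed(1)
  for (k in 1:25) expect_equal(sqrt(sum(random_force(0.2)^2)), 0.2)
  set.seed(123); a <- replicate(5, random_force(0.2))
  set.seed(123); b <- replicate(5, random_force(0.2))
  expect_identical(a, b)
  # no systematic axis bias (the normalized-cube scheme is symmetric about 0)
  set.seed(77)
  u <- matrix(runif(3 * 20000, -1, 1), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  expect_true(all(abs(colMeans(u)) < 4 / sqrt(nrow(u))))
  # but it is not isotropic: cube corners are over-represented
  expect_gt(mean(abs(u[, 1]) > 0.55), mean(abs(u[, 1]) < 0.1) * 0.9)
})

test_that("total force is the exact sum of the six rule forces", {
  set.seed(21)
  sc <- random_state(6, cfg0, seed = 21)
  sc$mode <- c("feeding", rep("standard", 5))
  pel <- pellet_field(x = runif(3, -0.5, 0.5), y = runif(3, -0.5, 0.5),
                      z = runif(3, 1, 1.5))
  f6 <- c(0.1, -0.05, 0.02)
  for (i in 1:6) {
    p <- perceive(sc, i, cfg0, pel)
    w <- cfg0$weights
    w5 <- if (sc$mode[i] == "feeding") w$w5_feeding else w$w5_standard
    manual <- separation_force(sc, i, p, w$w1) +
      cohesion_force(sc, i, p, w$w2) +
      alignment_force(sc, i, p, w$w3) +
      boundary_force(sc, i, p, w$w4, cfg0$tank) +
      feed_force(sc, i, p, w5) + f6
    expect_equal(total_force(sc, i, cfg0, pel, f6 = f6), manual)
  }
  # isolated fish at the centre in standard mode: only the random term
  sc0 <- make_school(x = 0, y = 0, z = 0.75)
  expect_equal(total_force(sc0, 1, cfg0, NULL, f6 = f6), f6)
})

test_that("speed cap rescales to Cv * TL preserving direction", {
  w <- cfg0$weights
  expect_equal(cap_speed(c(1, 0, 0), "standard", 0.1408, w),
               c(1.5 * 0.1408, 0, 0))
  expect_equal(cap_speed(c(1, 0, 0), "feeding", 0.1408, w),
               c(0.9856, 0, 0))
  expect_equal(cap_speed(c(0.1, 0, 0), "standard", 0.1408, w), c(0.1, 0, 0))
  v <- c(0.3, -0.4, 0.5)
  capped <- cap_speed(v, "standard", 0.1408, w)
  expect_equal(sqrt(sum(capped^2)), 1.5 * 0.1408)
  expect_equal(capped / sqrt(sum(capped^2)), v / sqrt(sum(v^2)))
})

test_that("semi-implicit Euler step with clamping", {
  tank <- cfg0$tank
  w <- cfg0$weights
  # force-free drift
  st <- integrate_step(c(0, 0, 1), c(0.1, 0, 0), c(0, 0, 0), 38.53,
                       "standard", 0.1408, w, 0.025, tank)
  expect_equal(st$x, c(0.0025, 0, 1))
  expect_equal(st$v, c(0.1, 0, 0))
  # a = F / (m/1000): 3.853 / 0.03853 = 100 m/s^2, then capped
  st2 <- integrate_step(c(0, 0, 1), c(0, 0, 0), c(3.853, 0, 0), 38.53,
                        "standard", 0.1408, w, 0.025, tank)
  expect_equal(st2$v, c(1.5 * 0.1408, 0, 0))
  expect_equal(st2$x, c(1.5 * 0.1408 * 0.025, 0, 1))
  expect_error(integrate_step(c(0, 0, 1), c(0, 0, 0), c(NaN, 0, 0), 38.53,
                              "standard", 0.1408, w, 0.025, tank),
               "non-finite")
  # property: a step never leaves the tank
  set.seed(31)
  for (k in 1:2000) {
    r <- 1.499 * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    st3 <- integrate_step(
      x = c(r * cos(th), r * sin(th), runif(1, 0.001, 1.499)),
      v = runif(3, -1, 1), force = runif(3, -5, 5),
      mass = runif(1, 10, 300), mode = sample(c("standard", "feeding"), 1),
      tl = runif(1, 0.05, 0.3), weights = w, dt = 0.025, tank = tank)
    expect_true(sqrt(st3$x[1]^2 + st3$x[2]^2) <= 1.5 - 1e-3 + 1e-12)
    expect_true(st3$x[3] >= 1e-3 - 1e-12 && st3$x[3] <= 1.5 - 1e-3 + 1e-12)
  }
})

test_that("trajectory recording tracks the stepping engine", {
  cfg <- micro_config(n_fish = 3L)
  set.seed(17)
  sc <- init_school(cfg)
  set.seed(18)
  tr <- record_trajectory(sc, cfg, n_steps = 8L, every = 2L)
  expect_identical(nrow(tr), 3L * 4L)
  expect_identical(unique(tr$step), c(2L, 4L, 6L, 8L))
  # last recorded state equals the state reached by stepping directly
  set.seed(18)
  s2 <- sc
  smax <- smax_intake(s2$mass)
  for (s in 1:8) s2 <- step_school(s2, NULL, cfg, smax)$school
  last <- tr[tr$step == 8L, ]
  expect_equal(last$x, s2$x)
  expect_equal(last$vz, s2$vz)
})

test_that("rule forces have magnitude exactly their weight or zero", {
  set.seed(41)
  for (k in 1:20) {
    sc <- random_state(8, cfg0, seed = 100 + k)
    sc$mode <- sample(c("standard", "feeding"), 8, replace = TRUE)
    pel <- pellet_field(x = runif(4, -0.7, 0.7), y = runif(4, -0.7, 0.7),
                        z = runif(4, 0.2, 1.4))
    w <- cfg0$weights
    for (i in seq_len(8)) {
      p <- perceive(sc, i, cfg0, pel)
      mags <- c(
        sqrt(sum(separation_force(sc, i, p, w$w1)^2)),
        sqrt(sum(cohesion_force(sc, i, p, w$w2)^2)),
        sqrt(sum(alignment_force(sc, i, p, w$w3)^2)),
        sqrt(sum(boundary_force(sc, i, p, w$w4, cfg0$tank)^2)),
        sqrt(sum(feed_force(sc, i, p, 3.0)^2)))
      expect_true(all(vapply(seq_along(mags), function(j)
        isTRUE(all.equal(mags[j], c(0.6, 0.4, 0.4, 1.0, 3.0)[j])) ||
          mags[j] == 0, TRUE)))
    }
  }
})
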