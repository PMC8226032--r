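test_that("differential-drive kinematics: average and scaled difference", {
  expect_equal(motor_to_velocity(1, 1), list(v = 1, omega = 0))
  expect_equal(motor_to_velocity(0, 0), list(v = 0, omega = 0))
  expect_equal(motor_to_velocity(0, 1, radius = 4),
               list(v = 0.5, omega = 0.25))
})

test_that("pose update translates with the pre-step heading", {
  p <- pose(0, 0, 0)
  expect_equal(update_pose(p, v = 1, omega = 0, dt = 0.1),
               pose(0.1, 0, 0))
  p2 <- update_pose(pose(1, 2, 1), v = 0, omega = 0.5, dt = 0.1)
  expect_equal(p2[["x"]], 1)
  expect_equal(p2[["y"]], 2)
  expect_equal(p2[["phi"]], 1.05)
})

test_that("constant unequal motor outputs trace a circle of radius v/omega", {
  vel <- motor_to_velocity(0.2, 0.8)
  R_true <- vel$v / vel$omega
  # the Euler trajectory's radius error shrinks as dt -> 0
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    p <- pose(0, 0, 0)
    centre <- c(0, R_true)  # circle centre for a start at origin heading +x
    pts <- matrix(NA_real_, 200, 2)
    for (k in 1:200) {
      p <- update_pose(p, vel$v, vel$omega, dt)
      pts[k, ] <- p[c("x", "y")]
    }
    radii <- sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
    max(abs(radii - R_true))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05 * R_true)
})

test_that("sensor positions sit at +-45 degrees on the body perimeter", {
  b <- body_config()
  sp <- sensor_positions(pose(0, 0, 0), b)
  expect_equal(unname(sp[1, ]), 4 * c(cos(pi / 4), sin(pi / 4)))
  expect_equal(unname(sp[2, ]), 4 * c(cos(pi / 4), -sin(pi / 4)))
  # always at distance exactly radius from the centre, any pose
  for (phi in seq(0, 2 * pi, length.out = 7)) {
    sp <- sensor_positions(pose(3, -2, phi), b)
    d <- sqrt((sp[, 1] - 3)^2 + (sp[, 2] + 2)^2)
    expect_equal(unname(d), c(4, 4))
  }
  # rotating the body by pi rotates the sensor points by pi
  sp0 <- sensor_positions(pose(0, 0, 0.3), b)
  sp1 <- sensor_positions(pose(0, 0, 0.3 + pi), b)
  expect_equal(unname(sp1), unname(-sp0))
})

test_that("signal intensity follows the attenuation and shadow laws", {
  b <- body_config()
  rp <- pose(0, 0, 0)
  sensor <- c(4, 0)
  # zero emitter -> zero intensity
  expect_identical(signal_intensity(0, c(50, 3), sensor, rp, b), 0)
  # source straight ahead of the sensor at distance 10: 1/d^2
  expect_equal(signal_intensity(1, c(14, 0), sensor, rp, b), 0.01)
  # doubling the distance divides by 4
  i1 <- signal_intensity(1, c(14, 0), sensor, rp, b)
  i2 <- signal_intensity(1, c(24, 0), sensor, rp, b)
  expect_equal(i1 / i2, 4)
  # linear in emitter strength
  expect_equal(signal_intensity(0.25, c(14, 0), sensor, rp, b), i1 / 4)
  # monotonically non-increasing in distance along the sensor axis
  ds <- seq(0.5, 40, by = 0.5)
  ints <- vapply(ds, function(d) {
    signal_intensity(1, c(4 + d, 0), sensor, rp, b)
  }, numeric(1))
  expect_true(all(diff(ints) <= 0))
  expect_true(all(ints >= 0))
  # a source behind the sensor is occluded by the body
  front <- signal_intensity(1, c(14, 0), sensor, rp, b)
  back <- signal_intensity(1, c(-6, 0), sensor, rp, b)
  expect_equal(back, b$occlusion / 100)
  expect_lt(back, front)
  expect_error(signal_intensity(-1, c(14, 0), sensor, rp, b),
               "non-negative")
})

test_that("solitary and silent worlds produce zero sensor intensities", {
  w1 <- world_state(list(pose(0, 0, 0)), 1)
  expect_equal(sense_world(w1, 1), c(0, 0))
  w2 <- world_state(list(pose(0, 0, 0), pose(20, 0, 0)), c(0, 0))
  expect_equal(sense_world(w2, 1), c(0, 0))
  expect_equal(sense_world(w2, 2), c(0, 0))
  # with a live partner emitter the intensities are positive
  w3 <- world_state(list(pose(0, 0, 0), pose(20, 0, 0)), c(1, 1))
  expect_true(all(sense_world(w3, 1) > 0))
})

test_that("IE trials record identically-zero sensor input", {
  set.seed(21)
  p <- decode_genotype(random_genotype(2), 2)
  tr <- run_trial(make_trials("IE")[[1]], p, duration = 20)
  expect_true(all(tr$sensor1 == 0))
  expect_true(all(tr$sensor2 == 0))
})

test_that("the C++ engine matches the plain-R reference engine", {
  set.seed(8)
  for (n in 2:3) {
    ps <- list(decode_genotype(random_genotype(n), n),
               decode_genotype(random_genotype(n), n))
    spec <- make_trials("SE")[[2]]
    a <- run_trial(spec, ps, duration = 10, engine = "cpp")
    b <- run_trial(spec, ps, duration = 10, engine = "r")
    num <- vapply(a, is.numeric, logical(1))
    expect_equal(as.matrix(a[num]), as.matrix(b[num]),
                 tolerance = 1e-12)
  }
})

test_that("swapping agent labels permutes but does not change trajectories", {
  set.seed(9)
  pa <- decode_genotype(random_genotype(2), 2)
  pb <- decode_genotype(random_genotype(2), 2)
  spec12 <- make_trials("SE")[[3]]  # partner at (-20, 0)
  # same poses, same controllers, opposite listing order
  spec21 <- spec12
  spec21$poses <- rev(spec12$poses)
  t12 <- run_trial(spec12, list(pa, pb), duration = 30)
  t21 <- run_trial(spec21, list(pb, pa), duration = 30)
  a1 <- t12[t12$agent_id == 1, -2]
  a1_swapped <- t21[t21$agent_id == 2, -2]
  rownames(a1) <- rownames(a1_swapped) <- NULL
  expect_equal(a1, a1_swapped)
})

test_that("a left-right symmetric pair in mirror-symmetric geometry stays on the axis", {
  # sensor rows and motor columns equal -> controller invariant under
  # left-right reflection; theta = 0 geometry is mirror-symmetric about
  # the x axis, so both trajectories must remain on it
  sym <- make_params(2, w_rec = matrix(c(2, -1, 1, 0.5), 2, 2),
                     w_sens = rbind(c(1.5, -2), c(1.5, -2)),
                     w_act = cbind(c(2, 1), c(2, 1), c(0.5, -3)),
                     tau = 1.2, theta = 0.3, gain = 2, sensor_gain = 4)
  tr <- run_trial(make_trials("SE")[[1]], list(sym, sym), duration = 50)
  expect_lt(max(abs(tr$y)), 1e-9)
})
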