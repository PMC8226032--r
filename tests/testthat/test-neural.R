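test_that("sigmoid has the right fixed points, limits and values", {
  expect_identical(sigmoid(0), 0.5)
  expect_identical(sigmoid(Inf), 1)
  expect_identical(sigmoid(-Inf), 0)
  expect_equal(sigmoid(1), 0.7310585786, tolerance = 1e-10)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(sigmoid(x)) > 0))  # strictly increasing
})

test_that("sensor transform is a shared sigmoid of gain * I + bias", {
  p <- make_params(2, sensor_gain = 3, sensor_bias = 0)
  expect_equal(sensor_transform(0, p), c(0.5, 0.5))
  p2 <- make_params(2, sensor_gain = 1, sensor_bias = -2)
  expect_equal(sensor_transform(0, p2), rep(sigmoid(-2), 2))
  p3 <- make_params(2, sensor_gain = 2, sensor_bias = -1)
  expect_equal(sensor_transform(1, p3), rep(sigmoid(1), 2),
               tolerance = 1e-10)
  expect_equal(sensor_transform(1, p3)[1], 0.7310585786,
               tolerance = 1e-10)
  expect_error(sensor_transform(-0.1, p), "non-negative")
})

test_that("ctrnn_step performs the Euler leak update", {
  p <- make_params(2, tau = 1)
  s <- neural_state(p, y = c(1, 1))
  s1 <- ctrnn_step(s, c(0.5, 0.5), p, dt = 0.1)
  # zero weights: dy = dt/tau * (-y) regardless of inputs
  expect_equal(s1$y, c(0.9, 0.9))
  # y = 0, theta = 0 is a fixed point with output 0.5 for any gain
  pg <- make_params(2, gain = 3)
  sg <- neural_state(pg)
  for (i in 1:5) sg <- ctrnn_step(sg, c(0.5, 0.5), pg, dt = 0.1)
  expect_equal(sg$y, c(0, 0))
  expect_equal(sg$neuron_out, c(0.5, 0.5))
})

test_that("single self-coupled neuron converges to the root-finding fixed point", {
  w <- 2.5; g <- 1.3; th <- -0.4; I <- 0.6
  p <- make_params(1, w_rec = matrix(w, 1, 1),
                   w_sens = matrix(c(1, 0), 2, 1), gain = g, theta = th)
  # independent oracle: solve y = w * sigmoid(g (y + theta)) + I directly
  f <- function(y) y - w * sigmoid(g * (y + th)) - I
  y_star <- uniroot(f, c(-10, 10), tol = 1e-14)$root
  s <- neural_state(p)
  for (k in 1:5000) s <- ctrnn_step(s, c(I, 0), p, dt = 0.1)
  expect_lt(abs(s$y - y_star), 1e-9)
})

test_that("layer outputs stay in [0, 1] for arbitrary finite parameters", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:3, 1)
    p <- make_params(n, w_rec = matrix(rnorm(n * n, sd = 8), n, n),
                     w_sens = matrix(rnorm(2 * n, sd = 8), 2, n),
                     w_act = matrix(rnorm(3 * n, sd = 8), n, 3),
                     tau = runif(n, 1, 2), theta = rnorm(n, sd = 8),
                     gain = runif(n, 1, 5), sensor_gain = runif(1, 1, 5),
                     sensor_bias = rnorm(1, sd = 8))
    s <- neural_state(p)
    for (k in 1:50) s <- ctrnn_step(s, runif(2), p, dt = 0.1)
    vals <- c(s$sensor_out, s$neuron_out, s$actuator_out)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(is.finite(s$y)))
  }
})

test_that("with all-zero weights the state is constant after one step", {
  p <- make_params(3, theta = 0.7, gain = 2)
  s0 <- neural_state(p)  # y = 0
  s1 <- ctrnn_step(s0, c(0.9, 0.1), p, dt = 0.1)
  s2 <- ctrnn_step(s1, c(0.2, 0.8), p, dt = 0.1)
  expect_equal(s1$y, s2$y)
  expect_equal(s1$neuron_out, s2$neuron_out)
})

test_that("Euler trajectory converges to the linear closed form as dt shrinks", {
  # frozen drive: zero weights, sensor weight 1 with constant input I
  # gives tau * dy/dt = -y + I, y(t) = y0 e^{-t/tau} + (1 - e^{-t/tau}) I
  tau <- 1.5; I <- 0.8; y0 <- 2; t_end <- 3
  p <- make_params(1, w_sens = matrix(c(1, 0), 2, 1), tau = tau)
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    s <- neural_state(p, y = y0)
    for (k in seq_len(round(t_end / dt))) s <- ctrnn_step(s, c(I, 0), p, dt)
    abs(s$y - (y0 * exp(-t_end / tau) + (1 - exp(-t_end / tau)) * I))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # error shrinks with dt
  expect_lt(errs[3] / errs[1], 0.5)         # roughly first order
})

test_that("actuator transform evaluates the stateless sigmoid read-out", {
  p <- make_params(2)
  expect_equal(unname(actuator_transform(c(0.3, 0.9), p)),
               rep(0.5, 3))
  pb <- make_params(2, actuator_bias = 1.2)
  expect_equal(unname(actuator_transform(c(0, 0), pb)),
               rep(sigmoid(1.2), 3))
  pw <- make_params(2, w_act = cbind(c(2, -2), 0, 0))
  expect_equal(unname(actuator_transform(c(1, 0), pw))[1],
               0.8807970780, tolerance = 1e-10)
})

test_that("controller parameters survive a JSON round trip", {
  set.seed(5)
  p <- decode_genotype(runif(30, -1, 1), 3)
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  q <- params_from_json(path)
  expect_equal(q, p, tolerance = 1e-15)
})

test_that("invalid parameter shapes and values are rejected", {
  expect_error(make_params(2, tau = 0), "positive")
  expect_error(make_params(2, tau = -1), "positive")
  expect_error(make_params(2, gain = 0), "positive")
  expect_error(neural_params(2, matrix(0, 3, 3), matrix(0, 2, 2),
                             matrix(0, 2, 3)), "w_rec")
})
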