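#' Canonical dynamical-system time series
#'
#' Deterministic generators for the reference series used to validate
#' the entropy and embedding estimators: a sine wave (limit cycle, known
#' quarter-period mutual-information minimum), the Henon map (`a = 1.4`,
#' `b = 0.3`; attractor embeds in dimension 2), the Lorenz system
#' (`sigma = 10`, `rho = 28`, `beta = 8/3`, integrated with
#' \pkg{deSolve} at `dt = 0.01`; x-coordinate, embeds in dimension 3)
#' and white Gaussian noise (no finite embedding dimension).
#'
#' @param system One of `"sine"`, `"henon"`, `"lorenz"`,
#'   `"white_noise"`.
#' @param length Number of samples returned (after the transient for the
#'   chaotic systems); at least 100.
#' @param params Named list overriding system parameters: sine `period`
#'   (samples, default 100), `amplitude`, `phase`, `noise` (sd of
#'   additive Gaussian observation noise, default 0; a small value makes
#'   the histogram MI estimator behave like the continuous theory);
#'   henon `a`, `b`,
#'   `transient` (default 100); lorenz `sigma`, `rho`, `beta`, `dt`,
#'   `transient` (steps, default 1000); white_noise `sd`.
#' @param seed RNG seed; only `white_noise` consumes randomness, the
#'   other systems are deterministic.
#' @return Numeric vector of length `length`.
#' @export
generate_fixture <- function(system = c("sine", "henon", "lorenz",
                                        "white_noise"),
                             length = 1000, params = list(),
                             seed = NULL) {
  system <- match.arg(system)
  length <- as.integer(length)
  if (length < 100L) stop("`length` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  p <- function(name, default) params[[name]] %||% default
  switch(system,
    sine = {
      period <- p("period", 100)
      x <- p("amplitude", 1) *
        sin(2 * pi * (seq_len(length) - 1) / period + p("phase", 0))
      noise <- p("noise", 0)
      if (noise > 0) x <- x + rnorm(length, sd = noise)
      x
    },
    henon = {
      a <- p("a", 1.4)
      b <- p("b", 0.3)
      transient <- p("transient", 100L)
      n <- length + transient
      x <- numeric(n)
      y <- numeric(n)
      x[1] <- p("x0", 0.1)
      y[1] <- p("y0", 0.1)
      for (t in seq_len(n - 1L)) {
        x[t + 1L] <- 1 - a * x[t]^2 + y[t]
        y[t + 1L] <- b * x[t]
      }
      x[(transient + 1L):n]
    },
    lorenz = {
      dt <- p("dt", 0.01)
      transient <- p("transient", 1000L)
      pars <- c(sigma = p("sigma", 10), rho = p("rho", 28),
                beta = p("beta", 8 / 3))
      deriv <- function(t, state, parms) {
        with(as.list(c(state, parms)), {
          list(c(sigma * (y - x), x * (rho - z) - y, x * y - beta * z))
        })
      }
      times <- seq(0, (length + transient - 1L) * dt, by = dt)
      sol <- deSolve::ode(c(x = 1, y = 1, z = 1), times, deriv, pars,
                          method = "ode45")
      sol[(transient + 1L):(transient + length), "x"]
    },
    white_noise = rnorm(length, sd = p("sd", 1))
  )
}
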