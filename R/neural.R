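#' Logistic sigmoid
#'
#' The activation function used by every node in the controller: sensor
#' nodes, CTRNN neurons and actuator nodes. Saturates smoothly at 0 and 1
#' for large negative / positive arguments.
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise, in `(0, 1)`.
#' @export
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(c(-Inf, Inf))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct and validate CTRNN controller parameters
#'
#' A controller has three fully connected layers: two sigmoidal sensor
#' nodes, `n_neurons` fully recurrently connected CTRNN neurons, and three
#' stateless sigmoidal actuator nodes (left motor, right motor, acoustic
#' emitter). Weight matrices are oriented source-by-target: `w_rec[j, i]`
#' is the weight from neuron `j` to neuron `i`, `w_sens[k, i]` from sensor
#' `k` to neuron `i`, and `w_act[i, k]` from neuron `i` to actuator `k`.
#'
#' Per-neuron time constants, biases and gains may be supplied as scalars
#' (shared across neurons, the default decoded layout) or as length-`n`
#' vectors. Gains are applied inside the output nonlinearity,
#' `sigma(gain * (y + theta))`, the usual convention for evolved CTRNNs.
#'
#' @param n_neurons Number of CTRNN neurons (2 or 3 in the standard models).
#' @param w_rec `n x n` recurrent weight matrix.
#' @param w_sens `2 x n` sensor-to-neuron weight matrix.
#' @param w_act `n x 3` neuron-to-actuator weight matrix; actuator order is
#'   fixed as (left motor, right motor, emitter).
#' @param tau Neuron time constant(s), simulation seconds, strictly positive.
#' @param theta Neuron bias(es).
#' @param gain Neuron output gain(s), strictly positive.
#' @param sensor_gain,sensor_bias Shared sensor-node sigmoid parameters.
#' @param actuator_bias Shared actuator-node bias.
#' @return An object of class `neural_params`.
#' @seealso [decode_genotype()] for the evolvable-genotype layout.
#' @export
neural_params <- function(n_neurons, w_rec, w_sens, w_act,
                          tau = 1, theta = 0, gain = 1,
                          sensor_gain = 1, sensor_bias = 0,
                          actuator_bias = 0) {
  n <- as.integer(n_neurons)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n_neurons` must be a single positive integer")
  w_rec <- as.matrix(w_rec)
  w_sens <- as.matrix(w_sens)
  w_act <- as.matrix(w_act)
  if (!identical(dim(w_rec), c(n, n)))
    stop("`w_rec` must be ", n, " x ", n)
  if (!identical(dim(w_sens), c(2L, n)))
    stop("`w_sens` must be 2 x ", n)
  if (!identical(dim(w_act), c(n, 3L)))
    stop("`w_act` must be ", n, " x 3")
  tau <- rep_len(as.numeric(tau), n)
  theta <- rep_len(as.numeric(theta), n)
  gain <- rep_len(as.numeric(gain), n)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all time constants `tau` must be finite and strictly positive")
  if (any(!is.finite(gain)) || any(gain <= 0))
    stop("all neuron gains must be finite and strictly positive")
  vals <- c(w_rec, w_sens, w_act, theta, sensor_gain, sensor_bias,
            actuator_bias)
  if (any(!is.finite(vals)))
    stop("all controller parameters must be finite")
  structure(
    list(n_neurons = n, w_rec = w_rec, w_sens = w_sens, w_act = w_act,
         tau = tau, theta = theta, gain = gain,
         sensor_gain = as.numeric(sensor_gain),
         sensor_bias = as.numeric(sensor_bias),
         actuator_bias = as.numeric(actuator_bias)),
    class = "neural_params")
}

#' @export
print.neural_params <- function(x, ...) {
  cat("CTRNN controller:", x$n_neurons, "neurons\n")
  cat("  tau  :", format(x$tau, digits = 4), "\n")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  cat("  gain :", format(x$gain, digits = 4), "\n")
  cat("  sensor gain/bias:", format(c(x$sensor_gain, x$sensor_bias),
                                    digits = 4), "\n")
  invisible(x)
}

#' Initialize the neural state of a controller
#'
#' Neuron potentials start at `y` (zero by default); the layer outputs are
#' the ones the controller would produce from that potential with zero
#' sensor intensity.
#'
#' @param params A [neural_params()] object.
#' @param y Initial neuron potentials (recycled to length `n_neurons`).
#' @return An object of class `neural_state` with fields `y`, `sensor_out`,
#'   `neuron_out` and `actuator_out`; all `*_out` fields lie in `[0, 1]`.
#' @export
neural_state <- function(params, y = 0) {
  stopifnot(inherits(params, "neural_params"))
  y <- rep_len(as.numeric(y), params$n_neurons)
  if (any(!is.finite(y))) stop("initial potentials must be finite")
  out <- sigmoid(params$gain * (y + params$theta))
  structure(
    list(y = y,
         sensor_out = sensor_transform(c(0, 0), params),
         neuron_out = out,
         actuator_out = actuator_transform(out, params)),
    class = "neural_state")
}

#' Sensor layer: acoustic intensity to sensor-node output
#'
#' Each of the two sensor nodes maps its received signal intensity through
#' a shared sigmoid, `sigma(sensor_gain * intensity + sensor_bias)`. With
#' zero intensity the nodes still output `sigma(sensor_bias)`.
#'
#' @param intensity Non-negative intensities; a scalar is recycled to both
#'   sensors.
#' @param params A [neural_params()] object.
#' @return Length-2 vector in `[0, 1]`.
#' @export
sensor_transform <- function(intensity, params) {
  intensity <- rep_len(as.numeric(intensity), 2L)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("sensor intensities must be finite and non-negative")
  sigmoid(params$sensor_gain * intensity + params$sensor_bias)
}

#' One Euler step of the CTRNN neuron layer
#'
#' Integrates the standard CTRNN state equation
#' \deqn{\tau_i \dot y_i = -y_i + \sum_j w^{rec}_{ji}\,
#'   \sigma(g_j (y_j + \theta_j)) + \sum_k w^{sens}_{ki}\, s_k}
#' with a forward Euler step of size `dt`, then recomputes the neuron and
#' actuator outputs from the updated potentials.
#'
#' @param state A `neural_state` (see [neural_state()]).
#' @param sensor_out Length-2 sensor-node outputs in `[0, 1]`.
#' @param params A [neural_params()] object.
#' @param dt Integration step, seconds (default 0.1, the simulation step).
#' @return The updated `neural_state`.
#' @export
ctrnn_step <- function(state, sensor_out, params, dt = 0.1) {
  y <- state$y
  sig <- sigmoid(params$gain * (y + params$theta))
  drive <- drop(crossprod(params$w_rec, sig)) +
    drop(crossprod(params$w_sens, sensor_out))
  y_new <- y + dt / params$tau * (-y + drive)
  if (any(!is.finite(y_new)))
    stop("CTRNN update produced a non-finite potential; ",
         "check parameter ranges")
  out <- sigmoid(params$gain * (y_new + params$theta))
  structure(
    list(y = y_new, sensor_out = sensor_out, neuron_out = out,
         actuator_out = actuator_transform(out, params)),
    class = "neural_state")
}

#' Actuator layer: neuron outputs to motor and emitter commands
#'
#' Stateless sigmoidal read-out:
#' `sigma(t(w_act) %*% neuron_out + actuator_bias)`. Index order is fixed
#' as (left motor, right motor, emitter).
#'
#' @param neuron_out Length-`n` neuron outputs in `[0, 1]`.
#' @param params A [neural_params()] object.
#' @return Named length-3 vector in `[0, 1]`.
#' @export
actuator_transform <- function(neuron_out, params) {
  out <- sigmoid(drop(crossprod(params$w_act, neuron_out)) +
                   params$actuator_bias)
  names(out) <- c("left", "right", "emitter")
  out
}

#' Serialize controller parameters to JSON
#'
#' Field names are fixed (`n_neurons`, `w_rec`, `w_sens`, `w_act`, `tau`,
#' `theta`, `gain`, `sensor_gain`, `sensor_bias`, `actuator_bias`);
#' matrices are stored row-wise as nested arrays at full precision.
#'
#' @param params A [neural_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) if written to file, else a JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "neural_params"))
  x <- unclass(params)
  json <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Deserialize controller parameters from JSON
#'
#' @param json A JSON string or a path to a JSON file written by
#'   [params_to_json()].
#' @return A validated [neural_params()] object.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  neural_params(n_neurons = x$n_neurons,
                w_rec = as.matrix(x$w_rec),
                w_sens = as.matrix(x$w_sens),
                w_act = as.matrix(x$w_act),
                tau = x$tau, theta = x$theta, gain = x$gain,
                sensor_gain = x$sensor_gain, sensor_bias = x$sensor_bias,
                actuator_bias = x$actuator_bias)
}
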