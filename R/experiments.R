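#' Trial initial conditions for the two evolutionary conditions
#'
#' Individual evolution (IE): a single agent at the origin heading right
#' (along +x); the four trials are identical by construction (the
#' simulation is deterministic and the solitary agent receives no input),
#' and are kept for structural parity with the social condition.
#'
#' Social evolution (SE): agent 1 at the origin heading right; agent 2 at
#' `distance` units from agent 1, at relative angle 0, pi/2, pi, 3*pi/2
#' for trials 1-4 in order, also heading right.
#'
#' @param condition `"IE"` or `"SE"`.
#' @param n_trials Number of trials (default 4).
#' @param distance Initial partner distance (SE; default 20).
#' @return List of trial specs, each of class `trial_spec` with fields
#'   `condition`, `trial` and `poses` (list of [pose()]s).
#' @export
make_trials <- function(condition = c("IE", "SE"), n_trials = 4,
                        distance = 20) {
  condition <- match.arg(condition)
  lapply(seq_len(n_trials), function(k) {
    poses <- list(pose(0, 0, 0))
    if (condition == "SE") {
      theta <- (k - 1) * pi / 2
      poses[[2]] <- pose(distance * cos(theta), distance * sin(theta), 0)
    }
    structure(list(condition = condition, trial = k, poses = poses),
              class = "trial_spec")
  })
}

# Fast path used inside the GA loop: returns only the neuron-output
# matrices (one T x n matrix per agent), skipping data-frame assembly.
.sim_outputs <- function(spec, params, cfg) {
  n_steps <- as.integer(round(cfg$trial_duration / cfg$dt))
  raw <- .sim_raw(spec, params, n_steps, cfg$dt, cfg$body,
                  sense_input = spec$condition == "SE")
  lapply(raw, `[[`, "out")
}

.sim_raw <- function(spec, params, n_steps, dt, body, sense_input,
                     engine = "cpp") {
  poses0 <- do.call(rbind, spec$poses)
  if (engine == "cpp") {
    .sim_trial_cpp(lapply(params, unclass), poses0, n_steps, dt,
                   body$radius, body$sensor_angles,
                   as.integer(body$attenuation == "inverse_square"),
                   as.integer(body$shadow == "hard"),
                   body$occlusion, body$min_distance, sense_input)
  } else {
    .sim_trial_r(params, spec$poses, n_steps, dt, body, sense_input)
  }
}

# Reference implementation in plain R, stepping the exported layer
# operations one at a time. Kept deliberately simple; the C++ engine is
# cross-checked against it in the test suite.
.sim_trial_r <- function(params, poses, n_steps, dt, body, sense_input) {
  na <- length(params)
  states <- lapply(params, neural_state)
  world <- world_state(poses,
                       vapply(states, function(s) s$actuator_out[["emitter"]],
                              numeric(1)))
  rec <- lapply(seq_len(na), function(a) {
    list(pose = matrix(NA_real_, n_steps, 3),
         sensors = matrix(NA_real_, n_steps, 2),
         y = matrix(NA_real_, n_steps, params[[a]]$n_neurons),
         out = matrix(NA_real_, n_steps, params[[a]]$n_neurons),
         act = matrix(NA_real_, n_steps, 3))
  })
  for (step in seq_len(n_steps)) {
    intensities <- lapply(seq_len(na), function(a) {
      sense_world(world, a, body, sense_input)
    })
    acts <- vector("list", na)
    for (a in seq_len(na)) {
      s_out <- sensor_transform(intensities[[a]], params[[a]])
      states[[a]] <- ctrnn_step(states[[a]], s_out, params[[a]], dt)
      acts[[a]] <- states[[a]]$actuator_out
    }
    world <- world_step(world, acts, body, dt)
    for (a in seq_len(na)) {
      rec[[a]]$pose[step, ] <- world$poses[[a]]
      rec[[a]]$sensors[step, ] <- intensities[[a]]
      rec[[a]]$y[step, ] <- states[[a]]$y
      rec[[a]]$out[step, ] <- states[[a]]$neuron_out
      rec[[a]]$act[step, ] <- acts[[a]]
    }
  }
  rec
}

#' Simulate one trial and record the full trace
#'
#' Runs the embodied simulation for `duration / dt` steps (2000 with the
#' default 200 s at dt = 0.1) with neuron potentials initialized at zero,
#' and returns a tidy per-step record.
#'
#' @param spec A trial spec from [make_trials()].
#' @param params A [neural_params()] object (IE) or a list of one or two
#'   of them (one per agent).
#' @param duration Trial length, simulation seconds.
#' @param dt Step size, seconds.
#' @param body A [body_config()].
#' @param sense_input If `FALSE`, sensor intensities are forced to zero
#'   (the decoupled testing mode). Defaults to `TRUE` only for
#'   two-agent trials; a solitary agent has no signal source.
#' @param engine `"cpp"` (fast, default) or `"r"` (reference
#'   implementation; identical results up to floating-point summation
#'   order).
#' @return A `simulation_trace`: a data frame with one row per agent and
#'   step, columns `time`, `agent_id`, `x`, `y`, `phi`, `sensor1`,
#'   `sensor2`, `emitter`, `left`, `right`, and per-neuron `y_i`,
#'   `out_i`.
#' @export
run_trial <- function(spec, params, duration = 200, dt = 0.1,
                      body = body_config(),
                      sense_input = length(spec$poses) == 2L,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(params, "neural_params")) params <- list(params)
  stopifnot(length(params) == length(spec$poses))
  n_steps <- as.integer(round(duration / dt))
  raw <- .sim_raw(spec, params, n_steps, dt, body, sense_input, engine)
  traces <- lapply(seq_along(raw), function(a) {
    r <- raw[[a]]
    n <- ncol(r$y)
    df <- data.frame(time = seq_len(n_steps) * dt, agent_id = a,
                     x = r$pose[, 1], y = r$pose[, 2], phi = r$pose[, 3],
                     sensor1 = r$sensors[, 1], sensor2 = r$sensors[, 2],
                     emitter = r$act[, 3], left = r$act[, 1],
                     right = r$act[, 2])
    for (i in seq_len(n)) df[[paste0("y_", i)]] <- r$y[, i]
    for (i in seq_len(n)) df[[paste0("out_", i)]] <- r$out[, i]
    df
  })
  out <- do.call(rbind, traces)
  class(out) <- c("simulation_trace", "data.frame")
  out
}

#' Post-evolution testing modes: coupled and decoupled
#'
#' Re-simulates an evolved solution for analysis. In `"decoupled"` mode
#' the chosen agent runs alone with its sensor input forced to zero
#' (`Input = 0`; the sensor nodes still output `sigma(sensor_bias)`). In
#' `"coupled"` mode an SE-evolved agent runs with its co-evolved partner
#' using the trial's initial geometry; an IE-evolved agent is paired with
#' a clone of itself (non-canonical, provided for completeness).
#'
#' @param record An `evolution_record` from [evolve_run()], or a raw
#'   genotype vector (then `condition` and `n_neurons` must be given).
#' @param mode `"coupled"` or `"decoupled"`.
#' @param trial Trial index used for the initial geometry (default 1).
#' @param agent Which agent of an SE pair to analyze/decouple (default 1).
#' @param condition,n_neurons,cfg Required when `record` is a raw
#'   genotype; taken from the record otherwise.
#' @param engine Simulation engine, see [run_trial()].
#' @return A `simulation_trace` (see [run_trial()]).
#' @export
test_mode <- function(record, mode = c("coupled", "decoupled"),
                      trial = 1, agent = 1, condition = NULL,
                      n_neurons = NULL, cfg = NULL,
                      engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  if (inherits(record, "evolution_record")) {
    genotype <- record$best_genotype
    condition <- record$condition
    n_neurons <- record$n_neurons
    cfg <- cfg %||% record$config
  } else {
    genotype <- record
    if (is.null(condition) || is.null(n_neurons))
      stop("`condition` and `n_neurons` are required for a raw genotype")
    cfg <- cfg %||% ga_config()
  }
  L <- genotype_length(n_neurons)
  params <- if (condition == "SE") {
    list(decode_genotype(genotype[seq_len(L)], n_neurons, cfg$ranges),
         decode_genotype(genotype[L + seq_len(L)], n_neurons,
                         cfg$ranges))
  } else {
    list(decode_genotype(genotype, n_neurons, cfg$ranges))
  }
  if (mode == "decoupled") {
    spec <- make_trials("IE", max(trial, 4L))[[trial]]
    run_trial(spec, params[[min(agent, length(params))]],
              duration = cfg$trial_duration, dt = cfg$dt,
              body = cfg$body, sense_input = FALSE,
              engine = match.arg(engine))
  } else {
    pair <- if (condition == "SE") params else list(params[[1]],
                                                    params[[1]])
    spec <- make_trials("SE", max(trial, 4L),
                        cfg$partner_distance)[[trial]]
    run_trial(spec, pair, duration = cfg$trial_duration, dt = cfg$dt,
              body = cfg$body, sense_input = TRUE,
              engine = match.arg(engine))
  }
}
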