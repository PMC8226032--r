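#' Scaling ranges for decoding genotypes
#'
#' Each genotype value in `[-1, 1]` is mapped linearly onto the range of
#' its parameter class. Defaults: connection weights `[-8, 8]`, biases
#' `[-8, 8]`, time constants `[1, 2]` seconds, gains `[1, 5]`.
#'
#' @param weights,biases,taus,gains Length-2 `c(min, max)` ranges.
#' @return An object of class `scaling_ranges`.
#' @export
scaling_ranges <- function(weights = c(-8, 8), biases = c(-8, 8),
                           taus = c(1, 2), gains = c(1, 5)) {
  rng <- list(weights = weights, biases = biases, taus = taus,
              gains = gains)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("range `", nm, "` must be c(min, max) with min < max")
  }
  if (rng$taus[1] <= 0) stop("tau range must be strictly positive")
  structure(rng, class = "scaling_ranges")
}

#' Number of evolvable parameters of one agent
#'
#' The default layout evolves all `n^2` recurrent weights, `2n` sensor
#' weights and `3n` actuator weights individually, plus 6 scalars shared
#' across units (neuron tau, neuron bias, neuron gain, sensor gain,
#' sensor bias, actuator bias): `n^2 + 5n + 6`, i.e. 20 parameters for
#' the 2-neuron model and 30 for the 3-neuron model.
#'
#' @param n_neurons 2 or 3 (other sizes are allowed but non-standard).
#' @return Integer genotype length for one agent.
#' @export
genotype_length <- function(n_neurons) {
  n <- as.integer(n_neurons)
  stopifnot(n >= 1L)
  n * n + 2L * n + 3L * n + 6L
}

#' Decode a genotype into controller parameters
#'
#' Applies the linear map `v -> min + (v + 1) / 2 * (max - min)` per
#' parameter class. The fixed layout, in order, is: `n^2` recurrent
#' weights (column-major), `2n` sensor weights (column-major), `3n`
#' actuator weights (column-major), then the 6 shared scalars: neuron
#' tau, neuron bias, neuron gain, sensor gain, sensor bias, actuator
#' bias. Weight entries use the `weights` range; tau the `taus` range;
#' neuron gain and sensor gain the `gains` range; the three biases the
#' `biases` range.
#'
#' @param genotype Numeric vector of length [genotype_length()]`(n_neurons)`,
#'   all entries in `[-1, 1]`.
#' @param n_neurons Number of CTRNN neurons.
#' @param ranges A [scaling_ranges()] object.
#' @return A [neural_params()] object.
#' @export
decode_genotype <- function(genotype, n_neurons,
                            ranges = scaling_ranges()) {
  n <- as.integer(n_neurons)
  L <- genotype_length(n)
  if (length(genotype) != L)
    stop("genotype has length ", length(genotype), ", expected ", L,
         " for the ", n, "-neuron model")
  if (any(!is.finite(genotype)) || any(abs(genotype) > 1))
    stop("genotype values must lie in [-1, 1]")
  sc <- function(v, r) r[1] + (v + 1) / 2 * (r[2] - r[1])
  i <- 0L
  take <- function(k) {
    v <- genotype[(i + 1L):(i + k)]
    i <<- i + k
    v
  }
  w_rec <- matrix(sc(take(n * n), ranges$weights), n, n)
  w_sens <- matrix(sc(take(2L * n), ranges$weights), 2L, n)
  w_act <- matrix(sc(take(3L * n), ranges$weights), n, 3L)
  neural_params(n_neurons = n, w_rec = w_rec, w_sens = w_sens,
                w_act = w_act,
                tau = sc(take(1L), ranges$taus),
                theta = sc(take(1L), ranges$biases),
                gain = sc(take(1L), ranges$gains),
                sensor_gain = sc(take(1L), ranges$gains),
                sensor_bias = sc(take(1L), ranges$biases),
                actuator_bias = sc(take(1L), ranges$biases))
}

#' Genetic-algorithm and evaluation configuration
#'
#' The `"full"` scale is the reference experimental setup: population 96,
#' 2000 generations, 10 runs per condition. The `"desk"` scale
#' (population 24, 200 generations, 5 runs) reproduces the qualitative
#' effects on a single workstation and is used by the package's own
#' replication checks.
#'
#' @param scale `"full"` or `"desk"` preset; individual arguments
#'   override the preset.
#' @param population Population size.
#' @param generations Number of generations.
#' @param runs Independent evolutionary runs per experimental cell.
#' @param elite_fraction Fraction of top solutions copied unchanged
#'   (elite count is the ceiling of `elite_fraction * population`).
#' @param mutation_variance Variance of the zero-mean Gaussian mutation
#'   noise added to every gene.
#' @param crossover_prob Probability of swapping each gene between the
#'   two parents.
#' @param trials Evaluation trials per solution.
#' @param trial_duration Trial length, simulation seconds.
#' @param dt Integration step, seconds.
#' @param bins Entropy bins per dimension (see [multidim_entropy()]).
#' @param burn_in Samples discarded before the entropy histogram.
#' @param ranges A [scaling_ranges()] object.
#' @param body A [body_config()] object.
#' @param partner_distance Initial partner distance in social trials.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(scale = c("full", "desk"), population = NULL,
                      generations = NULL, runs = NULL,
                      elite_fraction = 0.04, mutation_variance = 0.1,
                      crossover_prob = 0.1, trials = 4,
                      trial_duration = 200, dt = 0.1, bins = 50,
                      burn_in = 0, ranges = scaling_ranges(),
                      body = body_config(), partner_distance = 20) {
  scale <- match.arg(scale)
  preset <- switch(scale,
                   full = list(population = 96L, generations = 2000L,
                               runs = 10L),
                   desk = list(population = 24L, generations = 200L,
                               runs = 5L))
  population <- as.integer(population %||% preset$population)
  generations <- as.integer(generations %||% preset$generations)
  runs <- as.integer(runs %||% preset$runs)
  stopifnot(population >= 2L, generations >= 1L, runs >= 1L,
            elite_fraction > 0, elite_fraction <= 1,
            mutation_variance >= 0, crossover_prob >= 0,
            crossover_prob <= 1, trials >= 1L, trial_duration > 0,
            dt > 0)
  structure(list(scale = scale, population = population,
                 generations = generations, runs = runs,
                 elite_fraction = elite_fraction,
                 mutation_variance = mutation_variance,
                 crossover_prob = crossover_prob,
                 trials = as.integer(trials),
                 trial_duration = trial_duration, dt = dt,
                 bins = as.integer(bins), burn_in = burn_in,
                 ranges = ranges, body = body,
                 partner_distance = partner_distance),
            class = "ga_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a solution's entropy fitness
#'
#' Runs the evaluation trials for the given condition and returns the
#' fitness: the mean per-trial normalized neural entropy for a solitary
#' agent (IE), or the mean of the two agents' fitnesses for a co-evolved
#' pair (SE, genotype of length `2 * L`). Evaluation is fully
#' deterministic given the genotype and condition.
#'
#' @param genotype Solution vector: length `L` (IE) or `2 * L` (SE),
#'   where `L = genotype_length(n_neurons)`.
#' @param condition `"IE"` (solitary) or `"SE"` (interacting pair).
#' @param n_neurons Number of CTRNN neurons per agent.
#' @param cfg A [ga_config()].
#' @param detail If `TRUE`, attach per-trial (and per-agent) entropies as
#'   attributes `per_trial` and `per_agent`.
#' @return Fitness in `[0, 1]`.
#' @export
evaluate_genotype <- function(genotype, condition = c("IE", "SE"),
                              n_neurons, cfg = ga_config(),
                              detail = FALSE) {
  condition <- match.arg(condition)
  L <- genotype_length(n_neurons)
  if (condition == "IE") {
    params <- list(decode_genotype(genotype, n_neurons, cfg$ranges))
  } else {
    if (length(genotype) != 2L * L)
      stop("an SE solution encodes a pair: expected length ", 2L * L)
    params <- list(decode_genotype(genotype[seq_len(L)], n_neurons,
                                   cfg$ranges),
                   decode_genotype(genotype[L + seq_len(L)], n_neurons,
                                   cfg$ranges))
  }
  trials <- make_trials(condition, cfg$trials, cfg$partner_distance)
  n_agents <- length(params)
  per_trial <- matrix(NA_real_, length(trials), n_agents)
  for (tr in seq_along(trials)) {
    outs <- .sim_outputs(trials[[tr]], params, cfg)
    for (a in seq_len(n_agents))
      per_trial[tr, a] <- multidim_entropy(outs[[a]], cfg$bins,
                                           cfg$burn_in)
  }
  per_agent <- apply(per_trial, 2L, agent_fitness)
  fitness <- if (n_agents == 1L) per_agent[[1L]] else
    pair_fitness(per_agent[[1L]], per_agent[[2L]])
  if (detail) {
    attr(fitness, "per_trial") <- per_trial
    attr(fitness, "per_agent") <- per_agent
  }
  fitness
}

#' Produce the next GA generation
#'
#' The top `ceiling(elite_fraction * population)` solutions are copied
#' unchanged; every remaining slot is filled by choosing two distinct
#' elite parents uniformly (when at least two exist), swapping each gene
#' between them with probability `crossover_prob`, adding zero-mean
#' Gaussian noise of variance `mutation_variance` to every gene, and
#' clipping to `[-1, 1]`. Uses R's global RNG stream.
#'
#' @param population Matrix, one solution per row, values in `[-1, 1]`.
#' @param fitness Fitness vector, one value per row.
#' @param cfg A [ga_config()].
#' @return List with `population` (elites first, in fitness order),
#'   `n_elite`, and `elite_fitness` (fitness of the carried-over rows,
#'   valid without re-evaluation because evaluation is deterministic).
#' @export
next_generation <- function(population, fitness, cfg = ga_config()) {
  P <- nrow(population)
  L <- ncol(population)
  stopifnot(length(fitness) == P)
  ord <- order(fitness, decreasing = TRUE)
  n_elite <- ceiling(cfg$elite_fraction * P)
  elite <- population[ord[seq_len(n_elite)], , drop = FALSE]
  sdm <- sqrt(cfg$mutation_variance)
  children <- matrix(NA_real_, P - n_elite, L)
  for (i in seq_len(P - n_elite)) {
    if (n_elite >= 2L) {
      par2 <- sample.int(n_elite, 2L, replace = FALSE)
    } else {
      par2 <- c(1L, 1L)
    }
    child <- elite[par2[1L], ]
    swap <- runif(L) < cfg$crossover_prob
    child[swap] <- elite[par2[2L], swap]
    child <- child + rnorm(L, mean = 0, sd = sdm)
    children[i, ] <- pmin(1, pmax(-1, child))
  }
  list(population = rbind(elite, children), n_elite = n_elite,
       elite_fitness = fitness[ord[seq_len(n_elite)]])
}

#' Run one evolutionary search
#'
#' Full GA loop for one experimental cell: random initial population in
#' `[-1, 1]`, deterministic entropy evaluation, elitist selection with
#' Gaussian mutation and gene-swap crossover. All randomness derives from
#' `seed`, so runs are bit-reproducible; elitism plus deterministic
#' evaluation makes the best fitness non-decreasing across generations.
#'
#' @param condition `"IE"` or `"SE"`.
#' @param n_neurons Number of CTRNN neurons per agent (2 or 3).
#' @param cfg A [ga_config()].
#' @param seed Integer RNG seed for this run.
#' @return An object of class `evolution_record`: a list with
#'   `condition`, `n_neurons`, `seed`, `config`, `history` (data frame
#'   with `generation`, `best`, `mean` fitness; generation 0 is the
#'   random initial population), `best_genotype` and `best_fitness`
#'   (from the final generation).
#' @export
evolve_run <- function(condition = c("IE", "SE"), n_neurons,
                       cfg = ga_config(), seed = 1L) {
  condition <- match.arg(condition)
  set.seed(seed)
  L1 <- genotype_length(n_neurons)
  L <- if (condition == "SE") 2L * L1 else L1
  P <- cfg$population
  population <- matrix(runif(P * L, -1, 1), P, L)
  fitness <- vapply(seq_len(P), function(i) {
    evaluate_genotype(population[i, ], condition, n_neurons, cfg)
  }, numeric(1))
  G <- cfg$generations
  history <- data.frame(generation = 0:G, best = NA_real_,
                        mean = NA_real_)
  history$best[1L] <- max(fitness)
  history$mean[1L] <- mean(fitness)
  for (gen in seq_len(G)) {
    ng <- next_generation(population, fitness, cfg)
    population <- ng$population
    fitness <- c(ng$elite_fitness,
                 vapply((ng$n_elite + 1L):P, function(i) {
                   evaluate_genotype(population[i, ], condition,
                                     n_neurons, cfg)
                 }, numeric(1)))
    history$best[gen + 1L] <- max(fitness)
    history$mean[gen + 1L] <- mean(fitness)
  }
  best <- which.max(fitness)
  structure(list(condition = condition, n_neurons = as.integer(n_neurons),
                 seed = as.integer(seed), config = cfg,
                 history = history,
                 best_genotype = population[best, ],
                 best_fitness = fitness[[best]]),
            class = "evolution_record")
}

#' @export
print.evolution_record <- function(x, ...) {
  cat(sprintf("Evolution run: %s, %d-neuron model, seed %d\n",
              x$condition, x$n_neurons, x$seed))
  cat(sprintf("  %d generations, population %d\n",
              x$config$generations, x$config$population))
  cat(sprintf("  best fitness: %.4f (initial %.4f)\n",
              x$best_fitness, x$history$best[1]))
  invisible(x)
}

#' Run a full 2x2 study (brain size x social condition)
#'
#' Runs `cfg$runs` independent evolutionary searches in each of the four
#' cells (IE/SE crossed with the given model sizes) with per-run seeds
#' derived deterministically from `seed`.
#'
#' @param cfg A [ga_config()]; `cfg$runs` controls runs per cell.
#' @param n_neurons Model sizes to cross with the conditions.
#' @param seed Base seed; run `r` of cell `c` uses
#'   `seed + 1000 * c + r`.
#' @param verbose Print one line per completed run.
#' @return List of `evolution_record`s with attributes recording the
#'   design; pass to [summarize_runs()].
#' @export
run_study <- function(cfg = ga_config("desk"), n_neurons = c(2L, 3L),
                      seed = 1L, verbose = FALSE) {
  cells <- expand.grid(condition = c("IE", "SE"), n_neurons = n_neurons,
                       stringsAsFactors = FALSE)
  records <- list()
  for (ci in seq_len(nrow(cells))) {
    for (r in seq_len(cfg$runs)) {
      run_seed <- as.integer(seed + 1000L * ci + r)
      rec <- evolve_run(cells$condition[ci], cells$n_neurons[ci], cfg,
                        run_seed)
      records[[length(records) + 1L]] <- rec
      if (verbose)
        message(sprintf("%s %d-neuron run %d/%d: best %.4f",
                        rec$condition, rec$n_neurons, r, cfg$runs,
                        rec$best_fitness))
    }
  }
  attr(records, "design") <- cells
  attr(records, "seed") <- seed
  records
}
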