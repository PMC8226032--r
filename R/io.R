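.run_schema_version <- 1L

# full-precision numeric formatting for text round-trips
.fmt17 <- function(x) sprintf("%.17g", x)

#' Save an evolution run to a directory
#'
#' Writes plain-text, diff-able artifacts: `config.json` (condition,
#' model size, seed, resolved GA configuration, schema version),
#' `fitness.csv` (per-generation best and mean fitness) and
#' `best_genotype.json`. Floats are stored at full precision so that
#' [load_run()] restores them exactly.
#'
#' @param record An `evolution_record` from [evolve_run()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(record, dir) {
  stopifnot(inherits(record, "evolution_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- record$config
  cfg_out <- list(
    schema_version = .run_schema_version,
    condition = record$condition,
    n_neurons = record$n_neurons,
    seed = record$seed,
    best_fitness = .fmt17(record$best_fitness),
    ga = lapply(unclass(cfg), function(v) {
      if (inherits(v, "scaling_ranges") || inherits(v, "body_config"))
        unclass(v)
      else v
    }))
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  h <- record$history
  fit <- data.frame(generation = h$generation, best = .fmt17(h$best),
                    mean = .fmt17(h$mean))
  write.csv(fit, file.path(dir, "fitness.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(values = .fmt17(record$best_genotype)),
                       file.path(dir, "best_genotype.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Load an evolution run saved with [save_run()]
#'
#' @param dir Run directory.
#' @return An `evolution_record`; numeric fields are restored exactly
#'   (full-precision text round-trip).
#' @export
load_run <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  fit_path <- file.path(dir, "fitness.csv")
  gen_path <- file.path(dir, "best_genotype.json")
  if (!file.exists(cfg_path)) stop("config.json not found in ", dir)
  if (!file.exists(fit_path)) stop("fitness.csv not found in ", dir)
  if (!file.exists(gen_path))
    stop("best_genotype.json not found in ", dir)
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), .run_schema_version))
    stop("run schema version ", meta$schema_version,
         " does not match supported version ", .run_schema_version)
  ga <- meta$ga
  cfg <- ga_config(scale = ga$scale, population = ga$population,
                   generations = ga$generations, runs = ga$runs,
                   elite_fraction = ga$elite_fraction,
                   mutation_variance = ga$mutation_variance,
                   crossover_prob = ga$crossover_prob,
                   trials = ga$trials,
                   trial_duration = ga$trial_duration, dt = ga$dt,
                   bins = ga$bins, burn_in = ga$burn_in,
                   ranges = do.call(scaling_ranges, ga$ranges),
                   body = do.call(body_config, as.list(ga$body)),
                   partner_distance = ga$partner_distance)
  h <- read.csv(fit_path)
  gt <- jsonlite::read_json(gen_path, simplifyVector = TRUE)
  structure(list(condition = meta$condition,
                 n_neurons = as.integer(meta$n_neurons),
                 seed = as.integer(meta$seed), config = cfg,
                 history = data.frame(generation = h$generation,
                                      best = as.numeric(h$best),
                                      mean = as.numeric(h$mean)),
                 best_genotype = as.numeric(gt$values),
                 best_fitness = as.numeric(meta$best_fitness)),
            class = "evolution_record")
}

#' Write a simulation trace as CSV
#'
#' @param trace A `simulation_trace` from [run_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  num <- vapply(trace, is.numeric, logical(1)) &
    !(names(trace) %in% c("agent_id"))
  out <- trace
  out[num] <- lapply(out[num], .fmt17)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A `simulation_trace` data frame.
#' @export
read_trace <- function(path) {
  out <- read.csv(path)
  class(out) <- c("simulation_trace", "data.frame")
  out
}
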