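#' Normalized multi-dimensional Shannon entropy of neural outputs
#'
#' The fitness measure of the evolutionary search. The joint time series
#' of the `n` neuron outputs (each in `[0, 1]`) is binned into
#' `bins^n` equal-width cells on the unit hypercube; the Shannon entropy
#' `H = -sum(p * log(p))` of the occupied cells is divided by its maximum
#' `log(bins^n)`, so the result lies in `[0, 1]`. Values exactly on the
#' upper edge fall in the last bin.
#'
#' Note that with `T` samples at most `T` cells can be occupied, so the
#' largest attainable value is `min(1, log(T) / (n * log(bins)))`; see the
#' methods vignette for how this ceiling interacts with comparisons
#' across brain sizes.
#'
#' @param x Numeric matrix, `T` samples by `n` dimensions, values in
#'   `[0, 1]` (a vector is treated as one dimension).
#' @param bins Bins per dimension, integer >= 2 (default 50).
#' @param burn_in Number of initial samples discarded before binning
#'   (default 0: no transient removed).
#' @param normalize If `FALSE`, return the raw entropy in nats.
#' @return Normalized entropy in `[0, 1]` (or raw entropy in nats).
#' @export
#' @examples
#' multidim_entropy(matrix(0.5, 100, 2))           # 0: one occupied cell
#' multidim_entropy(cbind(c(.1, .1, .6, .6), c(.1, .1, .6, .6)), bins = 2)
multidim_entropy <- function(x, bins = 50, burn_in = 0, normalize = TRUE) {
  x <- as.matrix(x)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be at least 2")
  if (burn_in > 0) x <- x[-seq_len(min(burn_in, nrow(x))), , drop = FALSE]
  if (nrow(x) == 0L) stop("empty series: no samples to bin")
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("all values must lie in [0, 1]")
  n <- ncol(x)
  idx <- pmin(floor(x * bins), bins - 1L)
  cell <- drop(idx %*% bins^(seq_len(n) - 1))
  counts <- rle(sort.int(cell, method = "radix"))$lengths
  p <- counts / nrow(x)
  H <- -sum(p * log(p))
  if (normalize) H / (n * log(bins)) else H
}

#' Aggregate per-trial entropies into an agent fitness
#'
#' The agent's fitness is the mean of its normalized neural entropy
#' across the independent evaluation trials (4 by default in the
#' evolutionary setup).
#'
#' @param trial_entropies Numeric vector of per-trial entropies in
#'   `[0, 1]`.
#' @return Mean entropy in `[0, 1]`.
#' @export
agent_fitness <- function(trial_entropies) {
  if (length(trial_entropies) < 1L || anyNA(trial_entropies) ||
      any(trial_entropies < 0) || any(trial_entropies > 1))
    stop("trial entropies must be a non-empty vector in [0, 1]")
  mean(trial_entropies)
}

#' Fitness of a co-evolved pair of agents
#'
#' In social evolution one genotype encodes both agents; the pair's
#' fitness is the arithmetic mean of the two agents' individual
#' entropy fitnesses, which keeps the scale comparable with solitary
#' agents.
#'
#' @param agent_a,agent_b Individual fitnesses in `[0, 1]`.
#' @return Mean of the two, in `[0, 1]`.
#' @export
pair_fitness <- function(agent_a, agent_b) {
  stopifnot(agent_a >= 0, agent_a <= 1, agent_b >= 0, agent_b <= 1)
  (agent_a + agent_b) / 2
}
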