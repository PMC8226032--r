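# Shared builders and independent oracles for the test suite.

# A controller with explicit, simple parameter values.
make_params <- function(n = 2, w_rec = matrix(0, n, n),
                        w_sens = matrix(0, 2, n),
                        w_act = matrix(0, n, 3), tau = 1, theta = 0,
                        gain = 1, sensor_gain = 1, sensor_bias = 0,
                        actuator_bias = 0) {
  neural_params(n, w_rec, w_sens, w_act, tau, theta, gain, sensor_gain,
                sensor_bias, actuator_bias)
}

random_genotype <- function(n_neurons, pair = FALSE) {
  L <- genotype_length(n_neurons) * (1L + pair)
  runif(L, -1, 1)
}

# Independent entropy oracle: cut()-based binning and table() counting,
# a completely different code path from the implementation.
naive_entropy <- function(x, bins, normalize = TRUE) {
  x <- as.matrix(x)
  breaks <- seq(0, 1, length.out = bins + 1)
  labs <- apply(x, 2, function(col) {
    as.integer(cut(col, breaks, include.lowest = TRUE, right = FALSE))
  })
  labs <- as.matrix(labs)
  labs[x == 1] <- bins  # upper edge belongs to the last bin
  key <- apply(labs, 1, paste, collapse = "|")
  p <- as.vector(table(key)) / nrow(x)
  H <- -sum(p * log(p))
  if (normalize) H / log(bins^ncol(x)) else H
}

# Independent brute-force FNN oracle built on dist().
fnn_r_oracle <- function(x, tau, m_max, rtol = 10, atol = 2,
                         theiler = tau) {
  T <- length(x)
  sigma <- sd(x)
  vapply(seq_len(m_max), function(m) {
    M <- T - m * tau
    emb <- sapply(0:(m - 1), function(j) x[(1:M) + j * tau])
    emb <- matrix(emb, nrow = M)
    D <- as.matrix(dist(emb))
    for (off in 0:theiler) {
      idx <- which(abs(row(D) - col(D)) == off)
      D[idx] <- Inf
    }
    nn <- apply(D, 1, which.min)
    Rm <- D[cbind(1:M, nn)]
    extra <- abs(x[(1:M) + m * tau] - x[nn + m * tau])
    false1 <- ifelse(Rm > 0, extra / Rm > rtol, extra > 0)
    false2 <- sqrt(Rm^2 + extra^2) / sigma > atol
    mean(false1 | false2)
  }, numeric(1))
}
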