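#' Time-lagged mutual information of a scalar series
#'
#' Histogram (equal-width binning) estimator of
#' `MI(tau) = sum p(a, b) * log(p(a, b) / (p(a) * p(b)))` between
#' `x[t]` and `x[t + tau]`, for `tau = 0, ..., tau_max`. `MI(0)` equals
#' the marginal entropy of the binned series. Used to choose the delay
#' for attractor reconstruction at the first local minimum of the curve
#' (see [select_delay()]).
#'
#' @param x Numeric series, much longer than `tau_max`.
#' @param tau_max Largest lag evaluated.
#' @param bins Number of equal-width bins over the series range
#'   (default 64).
#' @return Numeric vector of length `tau_max + 1`, named by lag; all
#'   values are >= 0 (up to floating point). A constant series yields an
#'   all-zero curve with attribute `constant = TRUE` and a warning.
#' @export
mutual_information_curve <- function(x, tau_max = 50, bins = 64) {
  x <- as.numeric(x)
  T <- length(x)
  if (T <= tau_max + 1L) stop("series too short for `tau_max`")
  if (bins < 2L) stop("`bins` must be at least 2")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant series: mutual information is identically zero")
    mi <- rep(0, tau_max + 1L)
    names(mi) <- 0:tau_max
    attr(mi, "constant") <- TRUE
    return(mi)
  }
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1L)
  mi <- vapply(0:tau_max, function(tau) {
    u <- b[seq_len(T - tau)]
    v <- b[seq_len(T - tau) + tau]
    joint <- tabulate(u + bins * v + 1L, nbins = bins * bins)
    n <- T - tau
    pj <- joint[joint > 0] / n
    pu <- tabulate(u + 1L, nbins = bins) / n
    pv <- tabulate(v + 1L, nbins = bins) / n
    # expand marginals on the occupied joint cells
    occ <- which(joint > 0) - 1L
    pu_occ <- pu[occ %% bins + 1L]
    pv_occ <- pv[occ %/% bins + 1L]
    sum(pj * log(pj / (pu_occ * pv_occ)))
  }, numeric(1))
  names(mi) <- 0:tau_max
  attr(mi, "constant") <- FALSE
  mi
}

#' Choose an embedding delay from a mutual-information curve
#'
#' Returns the smallest lag `tau >= 1` that is a strict local minimum of
#' the curve (`MI(tau - 1) > MI(tau) < MI(tau + 1)`). If no local minimum
#' exists, falls back to the first lag at which the curve drops below
#' `MI(0) / e`; if that never happens, returns the largest lag. The
#' fallback used is recorded in the `"method"` attribute
#' (`"local_min"`, `"drop_1e"` or `"tau_max"`).
#'
#' @param mi A curve from [mutual_information_curve()] (index 1 is
#'   lag 0).
#' @return Integer delay (in samples) with attribute `method`.
#' @export
select_delay <- function(mi) {
  stopifnot(length(mi) >= 3L)
  m <- as.numeric(mi)
  n <- length(m)
  for (tau in 1:(n - 2L)) {
    if (m[tau] > m[tau + 1L] && m[tau + 1L] < m[tau + 2L])
      return(structure(tau, method = "local_min"))
  }
  drop <- which(m < m[1L] / exp(1))
  if (length(drop) > 0L)
    return(structure(drop[1L] - 1L, method = "drop_1e"))
  structure(n - 1L, method = "tau_max")
}

#' False-nearest-neighbour fractions per embedding dimension
#'
#' For each candidate dimension `m = 1, ..., m_max` the series is
#' delay-embedded as `(x[t], x[t + tau], ..., x[t + (m - 1) * tau])`;
#' each point's nearest Euclidean neighbour is found exhaustively,
#' excluding temporal neighbours within the Theiler window. A neighbour
#' is declared false when the extra `(m + 1)`-th coordinate stretches the
#' pair by more than `rtol` relative to its `m`-dimensional distance, or
#' pushes the `(m + 1)`-dimensional distance beyond `atol` times the
#' attractor size (the series' standard deviation).
#'
#' @param x Numeric series.
#' @param tau Embedding delay in samples (>= 1), typically from
#'   [select_delay()].
#' @param m_max Largest dimension examined.
#' @param rtol Relative stretch threshold (default 10).
#' @param atol Absolute size threshold in attractor-size units
#'   (default 2).
#' @param theiler Theiler window: neighbours within this many samples in
#'   time are excluded (default `tau`).
#' @return Numeric vector of false-neighbour fractions in `[0, 1]`,
#'   named `m1, m2, ...`.
#' @export
fnn_fractions <- function(x, tau, m_max = 8, rtol = 10, atol = 2,
                          theiler = tau) {
  x <- as.numeric(x)
  tau <- as.integer(tau)
  m_max <- as.integer(m_max)
  stopifnot(tau >= 1L, m_max >= 1L)
  need <- m_max * tau + 2L * (theiler + 1L)
  if (length(x) <= need)
    stop("series too short: need more than ", need,
         " points for m_max = ", m_max, ", tau = ", tau,
         ", theiler = ", theiler)
  frac <- .fnn_cpp(x, tau, m_max, rtol, atol, as.integer(theiler))
  names(frac) <- paste0("m", seq_len(m_max))
  frac
}

#' Minimal embedding dimension of a scalar series
#'
#' Chooses the delay at the first local minimum of the time-lagged
#' mutual information (unless `tau` is given) and returns the smallest
#' dimension whose false-nearest-neighbour fraction falls below
#' `threshold`. If the fraction never falls below the threshold, the
#' dimension at the global minimum is returned with `saturated = TRUE`.
#' A (numerically) constant series is reported as dimension 1 with
#' `degenerate = TRUE`: a fixed-point attractor.
#'
#' @param x Numeric series.
#' @param tau Embedding delay; `NULL` (default) selects it via
#'   [mutual_information_curve()] and [select_delay()].
#' @param m_max,rtol,atol,theiler Passed to [fnn_fractions()];
#'   `theiler = NULL` means the chosen `tau`.
#' @param threshold FNN fraction below which the dimension is accepted
#'   (default 0.01).
#' @param tau_max,bins Passed to [mutual_information_curve()].
#' @return An object of class `embedding_result`: list with `m`, `tau`,
#'   `mi_curve`, `fnn`, `saturated`, `degenerate`, `delay_method`.
#' @export
embedding_dimension <- function(x, tau = NULL, m_max = 8, rtol = 10,
                                atol = 2, theiler = NULL,
                                threshold = 0.01, tau_max = 50,
                                bins = 64) {
  x <- as.numeric(x)
  if (sd(x) < 1e-12) {
    return(structure(list(m = 1L, tau = 1L, mi_curve = NULL,
                          fnn = NULL, saturated = FALSE,
                          degenerate = TRUE, delay_method = "degenerate"),
                     class = "embedding_result"))
  }
  mi <- NULL
  delay_method <- "fixed"
  if (is.null(tau)) {
    mi <- mutual_information_curve(x, tau_max = tau_max, bins = bins)
    tau <- select_delay(mi)
    delay_method <- attr(tau, "method")
  }
  tau <- max(1L, as.integer(tau))
  theiler <- theiler %||% tau
  fnn <- fnn_fractions(x, tau, m_max, rtol, atol, theiler)
  ok <- which(!is.na(fnn) & fnn < threshold)
  if (length(ok) > 0L) {
    m <- ok[1L]
    saturated <- FALSE
  } else {
    m <- which.min(fnn)
    saturated <- TRUE
  }
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 mi_curve = mi, fnn = fnn, saturated = saturated,
                 degenerate = FALSE, delay_method = delay_method),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Embedding: degenerate (constant series), m = 1\n")
    return(invisible(x))
  }
  cat(sprintf("Embedding: tau = %d (%s), m = %d%s\n", x$tau,
              x$delay_method, x$m,
              if (x$saturated) " (saturated: FNN never below threshold)"
              else ""))
  cat("  FNN fractions:", paste(sprintf("%.3f", x$fnn), collapse = " "),
      "\n")
  invisible(x)
}

#' Embedding-dimension analysis of the best evolved agents
#'
#' For each evolutionary run, re-simulates the best agent in the given
#' testing mode and estimates the embedding dimension of the neuron-1
#' potential trajectory (`y_1`, the "neural state") of trial 1: delay
#' from the first minimum of the mutual information, dimension from the
#' false-nearest-neighbour method.
#'
#' @param records List of `evolution_record`s (e.g. from [run_study()],
#'   possibly filtered to one cell).
#' @param mode `"coupled"` or `"decoupled"` (see [test_mode()]).
#' @param neuron Which neuron's series to analyze (default 1).
#' @param trial Trial index (default 1).
#' @param series `"potential"` (`y_i`, default) or `"output"`
#'   (`out_i`).
#' @param ... Passed to [embedding_dimension()].
#' @return Data frame with one row per run: `condition`, `n_neurons`,
#'   `seed`, `tau`, `m`, `saturated`, `degenerate`; the across-run mean
#'   dimension is in attribute `mean_m`.
#' @export
analyze_best_agents <- function(records, mode = c("coupled", "decoupled"),
                                neuron = 1, trial = 1,
                                series = c("potential", "output"), ...) {
  mode <- match.arg(mode)
  series <- match.arg(series)
  col <- paste0(if (series == "potential") "y_" else "out_", neuron)
  rows <- lapply(records, function(rec) {
    trace <- test_mode(rec, mode, trial = trial)
    x <- trace[trace$agent_id == 1, col]
    emb <- embedding_dimension(x, ...)
    data.frame(condition = rec$condition, n_neurons = rec$n_neurons,
               seed = rec$seed, tau = emb$tau, m = emb$m,
               saturated = emb$saturated, degenerate = emb$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_m") <- mean(out$m)
  out
}
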