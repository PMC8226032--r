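#' Balanced two-way ANOVA on best-of-run entropies
#'
#' Fixed-effects two-way ANOVA with interaction on the 2x2 design
#' (social condition crossed with model size), fitted with
#' [stats::aov()]. With the standard 10 runs per cell the residual
#' degrees of freedom are `40 - 4 = 36`. The design must be balanced;
#' outliers are never removed.
#'
#' @param table Data frame with columns `condition` (two levels, e.g.
#'   `"IE"`/`"SE"`), `neurons` (two levels, e.g. 2/3) and `entropy`.
#' @return List of class `anova_2x2`: `F_condition`, `F_neurons`,
#'   `F_interaction`, the corresponding p-values, `df` (named vector,
#'   effects and residual) and `zero_variance` (if all responses are
#'   identical the F statistics are undefined and returned as `NA`).
#' @export
two_way_anova <- function(table) {
  req <- c("condition", "neurons", "entropy")
  if (!all(req %in% names(table)))
    stop("`table` needs columns condition, neurons, entropy")
  condition <- factor(table$condition)
  neurons <- factor(table$neurons)
  if (nlevels(condition) != 2L || nlevels(neurons) != 2L)
    stop("both factors must have exactly two levels")
  counts <- table(condition, neurons)
  if (length(unique(as.vector(counts))) != 1L || any(counts < 2L))
    stop("design must be balanced with at least 2 runs per cell")
  df <- data.frame(entropy = table$entropy, condition = condition,
                   neurons = neurons)
  dfs <- c(condition = 1, neurons = 1, interaction = 1,
           residual = nrow(df) - 4)
  if (var(df$entropy) == 0) {
    return(structure(list(F_condition = NA_real_, F_neurons = NA_real_,
                          F_interaction = NA_real_,
                          p_condition = NA_real_, p_neurons = NA_real_,
                          p_interaction = NA_real_, df = dfs,
                          zero_variance = TRUE),
                     class = "anova_2x2"))
  }
  fit <- aov(entropy ~ condition * neurons, data = df)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  gv <- function(row, col) s[match(row, rn), col]
  structure(list(
    F_condition = gv("condition", "F value"),
    F_neurons = gv("neurons", "F value"),
    F_interaction = gv("condition:neurons", "F value"),
    p_condition = gv("condition", "Pr(>F)"),
    p_neurons = gv("neurons", "Pr(>F)"),
    p_interaction = gv("condition:neurons", "Pr(>F)"),
    df = c(condition = gv("condition", "Df"),
           neurons = gv("neurons", "Df"),
           interaction = gv("condition:neurons", "Df"),
           residual = gv("Residuals", "Df")),
    zero_variance = FALSE), class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  if (x$zero_variance) {
    cat("Two-way ANOVA: zero response variance, F undefined\n")
    return(invisible(x))
  }
  cat(sprintf("Two-way ANOVA (residual df = %d)\n", x$df[["residual"]]))
  cat(sprintf("  condition:   F(1, %d) = %.2f, p = %.4f\n",
              x$df[["residual"]], x$F_condition, x$p_condition))
  cat(sprintf("  neurons:     F(1, %d) = %.2f, p = %.4f\n",
              x$df[["residual"]], x$F_neurons, x$p_neurons))
  cat(sprintf("  interaction: F(1, %d) = %.2f, p = %.4f\n",
              x$df[["residual"]], x$F_interaction, x$p_interaction))
  invisible(x)
}

#' Bonferroni-corrected post-hoc t-test between two design cells
#'
#' Pooled-variance two-sample t-test between two cells of the design
#' table (by default social 2-neuron vs. solitary 3-neuron, the planned
#' comparison of interest), with the p-value multiplied by the number of
#' planned comparisons in the family (default 1) and capped at 1.
#'
#' @param table Design table as in [two_way_anova()].
#' @param cellA,cellB Named lists/vectors with `condition` and `neurons`
#'   selecting the two cells.
#' @param comparisons Bonferroni family size (default 1).
#' @return List with `t`, `df`, `p` (raw) and `p_bonferroni`.
#' @export
posthoc_ttest <- function(table,
                          cellA = list(condition = "SE", neurons = 2),
                          cellB = list(condition = "IE", neurons = 3),
                          comparisons = 1) {
  pick <- function(cell) {
    table$entropy[table$condition == cell$condition &
                    table$neurons == cell$neurons]
  }
  a <- pick(cellA)
  b <- pick(cellB)
  if (length(a) < 2L || length(b) < 2L)
    stop("both cells need at least 2 observations")
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (sp2 == 0) {
    t_stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
  } else {
    t_stat <- (mean(a) - mean(b)) /
      sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p,
       p_bonferroni = min(1, comparisons * p))
}

#' Build the design table from completed runs
#'
#' Deterministic aggregation of best-of-run fitnesses into the table
#' consumed by [two_way_anova()] and [posthoc_ttest()]: one row per run
#' with its condition, model size, seed and best final-generation
#' fitness (the pair's fitness for social runs). Rows are ordered by
#' condition, model size and seed, so the result is independent of the
#' input ordering.
#'
#' @param records List of `evolution_record`s, or a directory containing
#'   run subdirectories written by [save_run()].
#' @return Data frame with columns `condition`, `neurons`, `seed`,
#'   `entropy`.
#' @export
summarize_runs <- function(records) {
  if (is.character(records)) {
    dirs <- list.dirs(records, recursive = FALSE)
    if (length(dirs) == 0L) stop("no run directories found in ", records)
    records <- lapply(dirs, load_run)
  }
  out <- do.call(rbind, lapply(records, function(rec) {
    data.frame(condition = rec$condition, neurons = rec$n_neurons,
               seed = rec$seed, entropy = rec$best_fitness)
  }))
  out[order(out$condition, out$neurons, out$seed), , drop = FALSE]
}
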