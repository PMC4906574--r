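#' Benchmark validation runtime against sheet size
#'
#' For every combination of row count, error rate and replicate: generate a
#' valid simulated mapping sheet (24 columns by default), inject errors at
#' the requested rate, and time a full QIIME validation (walltime, seconds).
#' Timings are reported, never asserted against absolute values — they are
#' hardware-bound; the interesting property is the near-linear scaling shape.
#'
#' @param row_counts Integer vector of sheet sizes (data rows).
#' @param error_rates Numeric vector of injection rates in \[0, 1\].
#' @param replicates Timing replicates per combination.
#' @param seed Base seed; each combination derives its own sub-seed.
#' @param ruleset Rule set to time; defaults to the full [qiime_ruleset()].
#' @return A `sheet_benchmark` tibble with one row per timing point:
#'   `axis` (`"rows"`), `x`, `error_rate`, `replicate`, `runtime_s`, plus an
#'   `environment` attribute describing the R build.
#' @export
benchmark_rows <- function(row_counts = c(100, 1000, 10000),
                           error_rates = c(0, 0.05), replicates = 3,
                           seed = 1, ruleset = qiime_ruleset()) {
  stopifnot(length(row_counts) > 0, length(error_rates) > 0, replicates >= 1)
  grid <- tidyr::expand_grid(x = as.integer(row_counts),
                             error_rate = error_rates,
                             replicate = seq_len(replicates))
  runtime <- purrr::pmap_dbl(grid, function(x, error_rate, replicate) {
    sub_seed <- (seed * 7919 + x * 31 + round(error_rate * 1000) * 7 +
                   replicate) %% .Machine$integer.max
    g <- simulate_mapping_sheet(x, seed = sub_seed)
    if (error_rate > 0) g <- inject_errors(g, error_rate, seed = sub_seed + 1)$grid
    unname(system.time(validate(g, ruleset))["elapsed"])
  })
  new_benchmark(dplyr::mutate(grid, axis = "rows", runtime_s = runtime))
}

#' Benchmark validation runtime against rule count
#'
#' A single validation rule (identifying cells with invalid characters) is
#' applied an increasing number of times to one fixed valid simulated sheet
#' (1000 rows x 24 columns, 0% errors by default), so each added rule has a
#' fixed performance cost and the cost of growing a format can be compared.
#'
#' @param rule_counts Integer vector of rule-set sizes to time.
#' @param n_rows Size of the fixed valid sheet.
#' @param replicates Timing replicates per rule count.
#' @param seed Seed for the generated sheet.
#' @return A `sheet_benchmark` tibble (`axis == "rules"`).
#' @export
benchmark_rules <- function(rule_counts = c(1, 4, 16, 64), n_rows = 1000,
                            replicates = 3, seed = 1) {
  stopifnot(all(rule_counts >= 1))
  g <- simulate_mapping_sheet(n_rows, seed = seed)
  grid <- tidyr::expand_grid(x = as.integer(rule_counts),
                             replicate = seq_len(replicates))
  runtime <- purrr::pmap_dbl(grid, function(x, replicate) {
    rs <- replicated_char_ruleset(x)
    unname(system.time(validate(g, rs))["elapsed"])
  })
  new_benchmark(dplyr::mutate(grid, axis = "rules", error_rate = 0,
                              runtime_s = runtime))
}

# N independent copies of the invalid-characters rule (ids must stay unique
# within a rule set, hence the numeric suffix)
replicated_char_ruleset <- function(n, free_text_class = QIIME_FREE_TEXT_CLASS) {
  rules <- lapply(seq_len(n), function(k) {
    prim_character_class("all", free_text_class,
                         sprintf("cell_invalid_characters_%d", k),
                         severity = "warning")
  })
  ruleset("rule-scaling", "tsv", rules)
}

new_benchmark <- function(df) {
  df <- dplyr::select(df, "axis", "x", "error_rate", "replicate", "runtime_s")
  attr(df, "environment") <- R.version.string
  class(df) <- c("sheet_benchmark", class(df))
  df
}

#' Median runtimes of a benchmark
#'
#' @param bench A `sheet_benchmark`.
#' @return A tibble of median runtime per (`x`, `error_rate`).
#' @export
benchmark_medians <- function(bench) {
  dplyr::summarise(dplyr::as_tibble(bench),
                   runtime_s = stats::median(.data$runtime_s),
                   .by = c("x", "error_rate"))
}

#' Log-log scaling slope of a benchmark
#'
#' Fits `log10(median runtime) ~ log10(x)` and returns the slope; a value
#' near 1 means near-linear scaling of validation runtime in sheet rows (or
#' rule count).
#'
#' @param bench A `sheet_benchmark`.
#' @return The fitted slope (a single number).
#' @export
scaling_slope <- function(bench) {
  med <- benchmark_medians(bench)
  med <- dplyr::summarise(med, runtime_s = stats::median(.data$runtime_s),
                          .by = "x")
  med$runtime_s <- pmax(med$runtime_s, 1e-4) # guard against sub-resolution timings
  unname(stats::coef(stats::lm(log10(runtime_s) ~ log10(x), data = med))[2])
}

#' Plot a scaling benchmark
#'
#' @param object A `sheet_benchmark`.
#' @param ... Unused.
#' @return A ggplot of runtime versus the scaled axis on log-log axes, one
#'   line per error rate (points are replicates, lines join medians).
#' @method autoplot sheet_benchmark
#' @export
autoplot.sheet_benchmark <- function(object, ...) {
  med <- benchmark_medians(object)
  xlab <- if (object$axis[1] == "rows") "spreadsheet rows" else "validation rules"
  ggplot2::ggplot(med, ggplot2::aes(x = .data$x, y = .data$runtime_s,
                                    colour = factor(.data$error_rate))) +
    ggplot2::geom_point(data = dplyr::as_tibble(object), alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "validation runtime (s)",
                  colour = "error rate") +
    ggplot2::theme_minimal()
}
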