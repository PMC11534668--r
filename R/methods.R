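# tidy()/glance() accessors and plotting for signal results.

#' Tidy a signal table
#'
#' @param x `ror_signals` object from [detect_signals()].
#' @param ... unused.
#' @return plain tibble with one row per term: `term`, `level`, `estimate`
#'   (the ROR), `conf.low`, `conf.high`, `n_reports`, `evaluable`,
#'   `is_signal`.
#' @export
tidy.ror_signals <- function(x, ...) {
  as_tibble(x) |>
    select(term, level, estimate = ror, conf.low = ci_low,
           conf.high = ci_high, n_reports, evaluable, is_signal)
}

#' One-row summary of a signal analysis
#'
#' @param x `ror_signals` object from [detect_signals()].
#' @param ... unused.
#' @return one-row tibble: cohort sizes, terms tested (no multiplicity
#'   adjustment is applied, so this is the relevant context for the signal
#'   count), evaluable terms, signals found, and the minimum report count.
#' @export
glance.ror_signals <- function(x, ...) {
  tibble(n_target = attr(x, "n_target"),
         n_comparator = attr(x, "n_comparator"),
         n_terms_tested = attr(x, "n_terms_tested"),
         n_evaluable = sum(x$evaluable),
         n_signals = sum(x$is_signal),
         min_count = attr(x, "min_count"))
}

#' Tidy a Venn partition
#'
#' @param x `venn_partition` object.
#' @param ... unused.
#' @return tibble `(term, side)` with `side` in
#'   `c("unique_left", "shared", "unique_right")`.
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(term = c(x$unique_left, x$shared, x$unique_right),
         side = rep(c("unique_left", "shared", "unique_right"),
                    c(length(x$unique_left), length(x$shared),
                      length(x$unique_right))))
}

#' Forest plot of disproportionality signals
#'
#' Point estimates with 95% intervals on a log axis, the standard rendition
#' of a signal screen. Non-evaluable terms are omitted.
#'
#' @param object `ror_signals` object.
#' @param signals_only plot only flagged signals (default `FALSE`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ror_signals <- function(object, signals_only = FALSE, ...) {
  dat <- as_tibble(object) |> filter(evaluable)
  if (signals_only) dat <- filter(dat, is_signal)
  dat <- mutate(dat, term = stats::reorder(term, ror))
  ggplot(dat, aes(x = ror, y = term)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = ci_low, xmax = ci_high), height = 0.2) +
    geom_point(aes(colour = is_signal), size = 2) +
    scale_x_log10() +
    labs(x = "Reporting odds ratio (95% CI)", y = NULL,
         colour = "signal") +
    theme_minimal()
}

#' Bar chart of a frequency table
#'
#' @param object `freq_table` object.
#' @param top how many rows to show (default all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.freq_table <- function(object, top = Inf, ...) {
  dat <- as_tibble(object) |>
    arrange(desc(count)) |>
    head(top) |>
    mutate(label = stats::reorder(label, count))
  ggplot(dat, aes(x = count, y = label)) +
    ggplot2::geom_col(fill = "steelblue") +
    labs(x = sprintf("count (%s)", attr(object, "unit") %||% "n"), y = NULL) +
    theme_minimal()
}
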