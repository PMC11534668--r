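# Reporting odds ratio disproportionality analysis.
#
# For one term the 2x2 four-grid table is
#
#               term reported   term not reported
#   target            a                 b
#   comparator        c                 d
#
# counted at case level (a case counts once per term). The reporting odds
# ratio is ROR = (a/c) / (b/d) with Woolf-type 95% interval
# exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)); a signal is declared
# when the lower bound exceeds 1. Tables with a zero cell, or with fewer
# reports than the minimum count, are marked non-evaluable rather than
# patched (an optional Haldane-Anscombe +0.5 correction is available behind
# a flag, off by default).

#' Build a 2x2 contingency table for one term
#'
#' Case-level counting: `a` is the number of target-cohort cases with at
#' least one event for the term, `b` the remaining target cases, and `c`,
#' `d` the same for the comparator cohort. Overlapping cohorts would count
#' the same case on both margins and are a hard error.
#'
#' @param events event table from [map_events()].
#' @param term PT (or SOC) to count.
#' @param target_ids,comparator_ids caseid vectors defining the two disjoint
#'   cohorts.
#' @param level `"pt"` or `"soc"`: which event column `term` refers to.
#' @return one-row tibble `(term, level, a, b, c, d)`.
#' @export
build_contingency <- function(events, term, target_ids, comparator_ids,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  target_ids <- unique(target_ids)
  comparator_ids <- unique(comparator_ids)
  if (length(intersect(target_ids, comparator_ids)) > 0) {
    stopf("target and comparator cohorts overlap",
          class = "faersignal_cohort_error")
  }
  with_term <- unique(events$caseid[events[[level]] == term])
  a <- sum(target_ids %in% with_term)
  c_ <- sum(comparator_ids %in% with_term)
  tibble(term = term, level = level,
         a = a, b = length(target_ids) - a,
         c = c_, d = length(comparator_ids) - c_)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' Vectorized over tables. A table is evaluable only if all four cells are
#' positive (after the optional continuity correction) and `a >= min_count`;
#' non-evaluable tables get `NA` estimates and are never signals.
#'
#' @param a,b,c,d non-negative integer cell counts, or a data frame with
#'   columns `a`, `b`, `c`, `d` as `a` (then `b`, `c`, `d` must be missing).
#' @param min_count minimum number of target-cohort reports (`a`) for a term
#'   to be evaluable; default 3, a common pharmacovigilance screening
#'   convention.
#' @param correction `"none"` (default) or `"haldane"` (+0.5 to every cell
#'   when any cell is zero).
#' @return tibble with one row per table: cells, `ror`, `ci_low`, `ci_high`,
#'   `n_reports` (= `a`), `evaluable`, `is_signal` (lower bound > 1).
#' @export
#' @examples
#' compute_ror(20, 80, 10, 90)   # ROR 2.25, CI (0.994, 5.092): no signal
#' compute_ror(50, 950, 100, 8900) # ROR 4.68, CI (3.31, 6.62): signal
compute_ror <- function(a, b = NULL, c = NULL, d = NULL, min_count = 3,
                        correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  if (is.data.frame(a)) {
    stopifnot(is.null(b), is.null(c), is.null(d))
    tbl <- a
    stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
    a <- tbl$a; b <- tbl$b; c <- tbl$c; d <- tbl$d
  }
  if (any(c(a, b, c, d) < 0)) {
    stopf("contingency cells must be non-negative",
          class = "faersignal_table_error")
  }
  n_reports <- a
  if (correction == "haldane") {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
  }
  evaluable <- a > 0 & b > 0 & c > 0 & d > 0 & n_reports >= min_count
  ror <- ci_low <- ci_high <- rep(NA_real_, length(a))
  i <- which(evaluable)
  if (length(i) > 0) {
    est <- (a[i] / c[i]) / (b[i] / d[i])
    half <- 1.96 * sqrt(1 / a[i] + 1 / b[i] + 1 / c[i] + 1 / d[i])
    ror[i] <- est
    ci_low[i] <- exp(log(est) - half)
    ci_high[i] <- exp(log(est) + half)
  }
  tibble(a = a, b = b, c = c, d = d, ror = ror, ci_low = ci_low,
         ci_high = ci_high, n_reports = n_reports, evaluable = evaluable,
         is_signal = evaluable & ci_low > 1)
}

#' Detect disproportionality signals across all terms of a cohort
#'
#' Builds the 2x2 table for every term observed in the target cohort and
#' computes the ROR for each. Results are sorted by descending ROR among
#' evaluable terms (ties broken lexicographically by term), with
#' non-evaluable terms last.
#'
#' @inheritParams build_contingency
#' @inheritParams compute_ror
#' @return tibble of class `ror_signals`, one row per term:
#'   `(term, level, a, b, c, d, ror, ci_low, ci_high, n_reports, evaluable,
#'   is_signal)`. Attributes: `n_terms_tested`, `n_target`, `n_comparator`,
#'   `min_count` (no multiplicity adjustment is applied; the number of terms
#'   tested is reported instead).
#' @export
detect_signals <- function(events, target_ids, comparator_ids,
                           level = c("pt", "soc"), min_count = 3,
                           correction = c("none", "haldane")) {
  level <- match.arg(level)
  target_ids <- unique(target_ids)
  comparator_ids <- unique(comparator_ids)
  if (length(intersect(target_ids, comparator_ids)) > 0) {
    stopf("target and comparator cohorts overlap",
          class = "faersignal_cohort_error")
  }
  ev <- tibble(caseid = events$caseid, term = events[[level]]) |> distinct()
  target_counts <- ev |>
    filter(caseid %in% target_ids) |>
    count(term, name = "a")
  if (nrow(target_counts) == 0) {
    out <- compute_ror(integer(0), integer(0), integer(0), integer(0),
                       min_count = min_count)
    out <- bind_cols(tibble(term = character(0), level = character(0)), out)
    return(new_ror_signals(out, 0, length(target_ids),
                           length(comparator_ids), min_count))
  }
  comp_counts <- ev |>
    filter(caseid %in% comparator_ids, term %in% target_counts$term) |>
    count(term, name = "c")
  cells <- target_counts |>
    left_join(comp_counts, by = "term") |>
    mutate(c = coalesce(c, 0L),
           b = length(target_ids) - a,
           d = length(comparator_ids) - c)
  res <- bind_cols(tibble(term = cells$term, level = level),
                   compute_ror(select(cells, a, b, c, d),
                               min_count = min_count,
                               correction = correction))
  res <- res |>
    arrange(desc(evaluable), desc(ror), term)
  new_ror_signals(res, nrow(res), length(target_ids),
                  length(comparator_ids), min_count)
}

new_ror_signals <- function(x, n_terms, n_target, n_comparator, min_count) {
  structure(x, class = c("ror_signals", class(tibble())),
            n_terms_tested = n_terms, n_target = n_target,
            n_comparator = n_comparator, min_count = min_count)
}

#' Venn partition of the terms reported by two cohorts
#'
#' @param left_events,right_events event tables (or any data frames with the
#'   term column) for the two cohorts.
#' @param level term column, `"pt"` or `"soc"`.
#' @return list of class `venn_partition` with sorted character vectors
#'   `unique_left`, `shared`, `unique_right` (pairwise disjoint; their union
#'   is every term observed in either cohort).
#' @export
venn_partition <- function(left_events, right_events, level = "pt") {
  left <- unique(left_events[[level]])
  right <- unique(right_events[[level]])
  structure(list(unique_left = sort(setdiff(left, right)),
                 shared = sort(intersect(left, right)),
                 unique_right = sort(setdiff(right, left))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition: %d unique left / %d shared / %d unique right\n",
              length(x$unique_left), length(x$shared), length(x$unique_right)))
  invisible(x)
}

#' Signals among formulation-unique terms
#'
#' The formulation comparison of interest: PTs reported with only one of the
#' two formulations are tested for disproportionality, each formulation
#' cohort against the all-other-drugs background. Shared PTs are excluded.
#'
#' @param events event table covering all cohorts.
#' @param oral_ids,subcutaneous_ids caseids of the two formulation cohorts.
#' @param background_ids caseids of the background comparator (cases where
#'   the target drug is not the primary suspect).
#' @inheritParams compute_ror
#' @return list with `partition` (the [venn_partition()]) and `oral`,
#'   `subcutaneous`: `ror_signals` tables restricted to each formulation's
#'   unique PTs.
#' @export
unique_pt_signals <- function(events, oral_ids, subcutaneous_ids,
                              background_ids, min_count = 3,
                              correction = c("none", "haldane")) {
  part <- venn_partition(filter(events, caseid %in% oral_ids),
                         filter(events, caseid %in% subcutaneous_ids))
  oral <- detect_signals(filter(events, pt %in% part$unique_left |
                                  caseid %in% background_ids),
                         oral_ids, background_ids, level = "pt",
                         min_count = min_count, correction = correction)
  oral <- oral[oral$term %in% part$unique_left, ]
  subq <- detect_signals(filter(events, pt %in% part$unique_right |
                                  caseid %in% background_ids),
                         subcutaneous_ids, background_ids, level = "pt",
                         min_count = min_count, correction = correction)
  subq <- subq[subq$term %in% part$unique_right, ]
  list(partition = part, oral = oral, subcutaneous = subq)
}

#' Route-versus-route disproportionality for one term
#'
#' Tests whether a term (PT or SOC) is reported more often with the oral
#' formulation than the subcutaneous one: the oral cohort is the target and
#' the subcutaneous cohort the comparator, and the reported `ror_025`
#' (= `ci_low`) is the decision statistic.
#'
#' @param events event table.
#' @param term term to test.
#' @param oral_ids,subcutaneous_ids cohort caseids (disjoint).
#' @inheritParams build_contingency
#' @inheritParams compute_ror
#' @return one-row tibble: the contingency cells, `ror`, `ci_low`
#'   (`ror_025`), `ci_high`, `evaluable`, `is_signal`.
#' @export
route_vs_route_ror <- function(events, term, oral_ids, subcutaneous_ids,
                               level = c("pt", "soc"), min_count = 3) {
  level <- match.arg(level)
  tbl <- build_contingency(events, term, oral_ids, subcutaneous_ids,
                           level = level)
  bind_cols(select(tbl, term, level),
            compute_ror(select(tbl, a, b, c, d), min_count = min_count)) |>
    mutate(ror_025 = ci_low)
}

#' Export a signal table
#'
#' Writes the TSV rendition (`term, level, a, b, c, d, ror, ci_low, ci_high,
#' is_signal`) of a signal result.
#'
#' @param signals `ror_signals` tibble.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_signal_table <- function(signals, path) {
  signals |>
    as_tibble() |>
    select(term, level, a, b, c, d, ror, ci_low, ci_high, is_signal) |>
    write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Export a forest-plot-ready table
#'
#' One row per evaluable term with the point estimate and interval bounds,
#' the layout a forest-plot routine consumes directly.
#'
#' @param signals `ror_signals` tibble.
#' @param path output TSV path.
#' @param signals_only keep only flagged signals (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_forest_table <- function(signals, path, signals_only = TRUE) {
  out <- as_tibble(signals) |> filter(evaluable)
  if (signals_only) out <- filter(out, is_signal)
  out |>
    mutate(label = sprintf("%.2f (%.2f, %.2f)", ror, ci_low, ci_high)) |>
    select(term, n_reports, ror, ci_low, ci_high, label) |>
    write_tsv(path, progress = FALSE)
  invisible(path)
}
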