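# Descriptive frequency tables: demographics, SOC/PT frequencies,
# serious-outcome rates, onset summaries, and the FAERS-versus-reviews
# comparison.
#
# Every table carries its own denominator and counting unit, and every
# percentage is recomputed from the table's own counts with the package
# rounding convention (round half up, 2 decimals), so each emitted table is
# self-consistent.

new_freq_table <- function(x, denominator, unit) {
  structure(x, class = c("freq_table", class(tibble())),
            denominator = denominator, unit = unit)
}

freq_rows <- function(labels, denominator, unit, section = NULL) {
  counts <- table(labels, useNA = "no")
  tbl <- tibble(label = names(counts), count = as.integer(counts)) |>
    mutate(percent = percent_half_up(count, denominator))
  if (!is.null(section)) tbl <- bind_cols(tibble(section = section,
                                                 .rows = nrow(tbl)), tbl)
  new_freq_table(tbl, denominator, unit)
}

#' Build a frequency table from precomputed counts
#'
#' Applies the package percentage convention (round half up, 2 decimals) to
#' a set of labelled counts, e.g. the printed counts of a published table.
#'
#' @param labels character vector of row labels.
#' @param counts integer vector of counts.
#' @param denominator percentage denominator; defaults to `sum(counts)`.
#' @param unit counting unit (`"cases"`, `"events"`, `"reviews"`,
#'   `"review-events"`).
#' @return tibble of class `freq_table` with columns `label`, `count`,
#'   `percent`.
#' @export
#' @examples
#' frequency_table("Gastrointestinal disorders", 15704, denominator = 56048)
frequency_table <- function(labels, counts, denominator = sum(counts),
                            unit = "events") {
  stopifnot(length(labels) == length(counts), all(counts >= 0))
  new_freq_table(
    tibble(label = as.character(labels), count = as.integer(counts),
           percent = percent_half_up(counts, denominator)),
    denominator, unit)
}

age_band <- function(age_years) {
  case_when(is.na(age_years) ~ "unknown",
            age_years < 35 ~ "<35",
            age_years <= 65 ~ "35-65",
            TRUE ~ ">65")
}

sex_label <- function(sex) {
  case_when(sex %in% "M" ~ "male", sex %in% "F" ~ "female",
            TRUE ~ "unknown")
}

#' Demographic frequency tables for a case cohort
#'
#' One long table with a `section` column covering: report year (from the
#' received date `fda_dt`, since the yearly buckets describe report volume),
#' age band (`<35`, `35-65`, `>65`, `unknown`), sex, and the top
#' `country_top` reporter countries. All percentages use the full case count
#' as denominator, so the age bands and country rows need not sum to 100
#' (unknown age is its own band; countries are truncated).
#'
#' @param cases case table from [assemble_cases()].
#' @param country_top how many countries to keep (default 10).
#' @return `freq_table` tibble with columns `section`, `label`, `count`,
#'   `percent`; `attr(x, "denominator")` is the case count.
#' @export
demographics_table <- function(cases, country_top = 10) {
  n <- nrow(cases)
  if (n == 0) {
    return(new_freq_table(tibble(section = character(0),
                                 label = character(0), count = integer(0),
                                 percent = numeric(0)), 0, "cases"))
  }
  year <- freq_rows(faers_year(cases$fda_dt), n, "cases", "year")
  age <- freq_rows(factor(age_band(cases$age_years),
                          levels = c("<35", "35-65", ">65", "unknown")),
                   n, "cases", "age")
  sex <- freq_rows(factor(sex_label(cases$sex),
                          levels = c("male", "female", "unknown")),
                   n, "cases", "sex")
  country <- freq_rows(cases$country[!is.na(cases$country)], n, "cases",
                       "country") |>
    arrange(desc(count), label) |>
    head(country_top)
  new_freq_table(bind_rows(year, age, sex, country), n, "cases")
}

#' Demographic frequency tables for coded reviews
#'
#' The review analogue of [demographics_table()]: year of the review date,
#' age band, and sex, with the review count as denominator.
#'
#' @param reviews tibble from [read_coded_reviews()] or
#'   [simulate_coded_reviews()].
#' @return `freq_table` tibble with `section`, `label`, `count`, `percent`.
#' @export
review_demographics_table <- function(reviews) {
  n <- nrow(reviews)
  if (n == 0) {
    return(new_freq_table(tibble(section = character(0),
                                 label = character(0), count = integer(0),
                                 percent = numeric(0)), 0, "reviews"))
  }
  year <- freq_rows(substr(reviews$date, 1, 4), n, "reviews", "year")
  age <- freq_rows(factor(age_band(reviews$age),
                          levels = c("<35", "35-65", ">65", "unknown")),
                   n, "reviews", "age")
  sex <- freq_rows(factor(sex_label(reviews$sex),
                          levels = c("male", "female", "unknown")),
                   n, "reviews", "sex")
  new_freq_table(bind_rows(year, age, sex), n, "reviews")
}

#' SOC frequency table
#'
#' One row per System Organ Class, counted in (case, PT) events: a case with
#' several PTs in the same SOC contributes once per PT, which is the
#' counting unit under which published SOC tables sum to their event total.
#'
#' @param events event table from [map_events()].
#' @param denominator percentage denominator; defaults to the total event
#'   count, so percentages sum to ~100.
#' @return `freq_table` sorted by descending count (ties alphabetical).
#' @export
soc_frequency_table <- function(events, denominator = nrow(events)) {
  freq_rows(events$soc, denominator, "events") |>
    arrange(desc(count), label) |>
    new_freq_table(denominator, "events")
}

#' Top-k PT frequency table
#'
#' @param events event table from [map_events()].
#' @param top_k number of Preferred Terms to keep (default 30); ties on
#'   equal counts are broken alphabetically. Percentages keep the full
#'   (untruncated) event total as denominator.
#' @return `freq_table` with `top_k` rows.
#' @export
pt_frequency_table <- function(events, top_k = 30) {
  freq_rows(events$pt, nrow(events), "events") |>
    arrange(desc(count), label) |>
    head(top_k) |>
    new_freq_table(nrow(events), "events")
}

#' Serious-outcome rate of a cohort
#'
#' Fraction of cases with at least one outcome code in `serious_codes`.
#' The default set is every FAERS outcome code except `OT`
#' (`DE, LT, HO, DS, CA, RI`); a death/life-threatening-only analysis uses
#' `serious_codes = c("DE", "LT")`.
#'
#' @param cases case table (needs the `outcomes` list-column).
#' @param serious_codes outcome codes counted as serious.
#' @return one-row `freq_table`: `label`, `count`, `percent` over the case
#'   denominator.
#' @export
serious_outcome_rate <- function(cases,
                                 serious_codes = c("DE", "LT", "HO", "DS",
                                                   "CA", "RI")) {
  n <- nrow(cases)
  hit <- map_lgl(cases$outcomes, ~ any(.x %in% serious_codes))
  new_freq_table(
    tibble(label = "serious outcome", count = sum(hit),
           percent = percent_half_up(sum(hit), n)),
    n, "cases")
}

#' Time-to-onset summary
#'
#' Median and quartiles (linear-interpolation quantiles, [stats::quantile()]
#' type 7) of the usable per-case onsets. Exclusion counters from
#' [onset_days()] are carried through.
#'
#' @param cases case table after [onset_days()].
#' @return one-row tibble: `n_usable`, `median`, `q1`, `q3`,
#'   `n_negative_excluded`, `defined` (`FALSE` when no onset is usable).
#' @export
#' @examples
#' x <- tibble::tibble(onset_days = c(1L, 1L, 4L, 32L, 60L))
#' onset_summary(x) # median 4, Q1 1, Q3 32
onset_summary <- function(cases) {
  onsets <- cases$onset_days[!is.na(cases$onset_days)]
  n_neg <- attr(cases, "n_negative_excluded") %||% 0L
  if (length(onsets) == 0) {
    return(tibble(n_usable = 0L, median = NA_real_, q1 = NA_real_,
                  q3 = NA_real_, n_negative_excluded = n_neg,
                  defined = FALSE))
  }
  q <- unname(quantile(onsets, c(0.25, 0.5, 0.75), type = 7))
  tibble(n_usable = length(onsets), median = q[[2]], q1 = q[[1]],
         q3 = q[[3]], n_negative_excluded = n_neg, defined = TRUE)
}

#' Side-by-side comparison of two frequency-table sources
#'
#' Full join on (section, label) of e.g. a FAERS-derived table and its
#' coded-review analogue, with both percentage columns, their absolute
#' difference, and a flag for rows present in only one source.
#'
#' @param left,right `freq_table` tibbles (with or without a `section`
#'   column).
#' @param names length-2 labels for the two sources (used as column
#'   prefixes).
#' @return tibble with count/percent columns per source, `abs_diff`, and
#'   `only_in` (`NA` when present in both).
#' @export
compare_sources <- function(left, right, names = c("faers", "social")) {
  keys <- intersect(c("section", "label"), intersect(colnames(left),
                                                     colnames(right)))
  l <- as_tibble(left) |>
    rename_with(~ paste(names[[1]], .x, sep = "_"), c(count, percent))
  r <- as_tibble(right) |>
    rename_with(~ paste(names[[2]], .x, sep = "_"), c(count, percent))
  full_join(l, r, by = keys) |>
    mutate(
      abs_diff = abs(.data[[paste0(names[[1]], "_percent")]] -
                       .data[[paste0(names[[2]], "_percent")]]),
      only_in = case_when(
        is.na(.data[[paste0(names[[2]], "_count")]]) ~ names[[1]],
        is.na(.data[[paste0(names[[1]], "_count")]]) ~ names[[2]],
        TRUE ~ NA_character_
      )
    )
}

#' Export a frequency table
#'
#' TSV rendition; a Markdown rendition (`format = "markdown"`) is available
#' for reports.
#'
#' @param x `freq_table` tibble.
#' @param path output path.
#' @param format `"tsv"` (default) or `"markdown"`.
#' @return invisibly, `path`.
#' @export
write_freq_table <- function(x, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as_tibble(x), path, progress = FALSE)
  } else {
    tbl <- as_tibble(x)
    header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
    rows <- apply(tbl, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
    write_lines(c(header, sep, rows), path)
  }
  invisible(path)
}
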