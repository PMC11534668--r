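# From report versions to unique cases: deduplication, target-drug
# selection, table joining, onset computation.

#' Default target-drug name patterns
#'
#' Case-insensitive substring patterns matching semaglutide products in
#' FAERS free-text drug names.
#'
#' @return character vector of patterns.
#' @export
semaglutide_patterns <- function() {
  c("semaglutide", "ozempic", "wegovy", "rybelsus")
}

#' Select one report version per case
#'
#' A FAERS case may be reported several times; each version carries the same
#' `caseid` but its own `primaryid` and received date. The current version
#' is the one with the latest received date (`fda_dt`, missing treated as
#' earliest), with the numerically largest `primaryid` breaking ties. The
#' selection is idempotent and invariant to input order.
#'
#' @param demo tibble of demographic records (needs `primaryid`, `caseid`,
#'   `fda_dt`).
#' @return tibble with one row per `caseid`: the selected `primaryid` and
#'   its `fda_dt`.
#' @export
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("71", "72", "73"), caseid = "7",
#'   fda_dt = c(20220101L, 20220301L, 20220301L)
#' )
#' deduplicate_reports(demo)
deduplicate_reports <- function(demo) {
  demo |>
    mutate(.fda_key = coalesce(as.numeric(fda_dt), -Inf),
           .pid_key = as.numeric(primaryid)) |>
    group_by(caseid) |>
    arrange(.fda_key, .pid_key, .by_group = TRUE) |>
    slice_tail(n = 1) |>
    ungroup() |>
    arrange(caseid) |>
    select(caseid, primaryid, fda_dt)
}

#' Select cases with the target drug as primary suspect
#'
#' A case is included iff its selected report version has at least one drug
#' row with role code `PS` whose free-text `drugname` matches any pattern
#' (case-insensitive substring).
#'
#' @param drug tibble of drug records.
#' @param kept deduplication map from [deduplicate_reports()].
#' @param target_patterns non-empty character vector of name patterns
#'   (default [semaglutide_patterns()]).
#' @return character vector of caseids.
#' @export
select_target_cases <- function(drug, kept,
                                target_patterns = semaglutide_patterns()) {
  if (length(target_patterns) == 0) {
    stopf("target_patterns must be non-empty", class = "faersignal_config_error")
  }
  hits <- drug |>
    semi_join(kept, by = "primaryid") |>
    filter(role_cod == "PS",
           matches_any_pattern(drugname, target_patterns)) |>
    distinct(primaryid)
  kept |>
    semi_join(hits, by = "primaryid") |>
    pull(caseid)
}

# case-insensitive literal substring match against any pattern
matches_any_pattern <- function(x, patterns) {
  xl <- str_to_lower(x)
  hit <- rep(FALSE, length(x))
  for (p in str_to_lower(patterns)) {
    hit <- hit | str_detect(xl, fixed(p))
  }
  hit & !is.na(x)
}

age_to_years <- function(age, age_cod) {
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  # absent unit code with a recorded age is read as years (FAERS convention);
  # an unrecognized code makes the age unusable
  f <- ifelse(is.na(age_cod), 1, unname(factor_map[age_cod]))
  out <- age * f
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Assemble one record per unique case
#'
#' Joins the five FAERS tables at the selected report version of each case,
#' normalizes age to years (DEC x10, YR x1, MON /12, WK /52, DY /365.25,
#' HR /8766; unknown unit codes make the age unusable), and derives
#' `therapy_start` as the earliest day-precision start date among therapy
#' rows pointing at a target drug. Cases with no reactions violate the case
#' contract and are dropped with a warning (count in
#' `attr(x, "n_dropped_no_reaction")`).
#'
#' @param tables named list of the five tibbles (see [read_quarter()]).
#' @param kept deduplication map from [deduplicate_reports()].
#' @param caseids optional caseid subset (e.g. from
#'   [select_target_cases()]); default keeps all deduplicated cases.
#' @param target_patterns patterns identifying target-drug rows for the
#'   therapy-start join.
#' @return tibble with one row per case: identifiers, demographics,
#'   `drugs` (list-column of drug rows), `reactions` and `outcomes`
#'   (list-columns of distinct values), `therapy_start`, `n_drugs`,
#'   `n_reactions`.
#' @export
assemble_cases <- function(tables, kept, caseids = NULL,
                           target_patterns = semaglutide_patterns()) {
  if (!is.null(caseids)) kept <- filter(kept, caseid %in% caseids)
  demo <- tables$demo |>
    semi_join(kept, by = c("caseid", "primaryid")) |>
    distinct(caseid, .keep_all = TRUE)

  drug <- semi_join(tables$drug, kept, by = "primaryid")
  reac <- semi_join(tables$reac, kept, by = "primaryid")
  outc <- semi_join(tables$outc, kept, by = "primaryid")
  ther <- semi_join(tables$ther, kept, by = "primaryid")

  target_seqs <- drug |>
    filter(matches_any_pattern(drugname, target_patterns)) |>
    distinct(primaryid, drug_seq)
  ther_start <- ther |>
    inner_join(target_seqs, by = c("primaryid", "dsg_drug_seq" = "drug_seq")) |>
    filter(is_valid_day_date(start_dt)) |>
    group_by(primaryid) |>
    summarise(therapy_start = min(start_dt), .groups = "drop")

  drugs_nested <- drug |> arrange(primaryid, drug_seq) |>
    group_by(primaryid) |> summarise(drugs = list(pick(everything())),
                                     n_drugs = n(), .groups = "drop")
  reac_nested <- reac |> distinct(primaryid, pt) |> arrange(primaryid, pt) |>
    group_by(primaryid) |> summarise(reactions = list(pt),
                                     n_reactions = n(), .groups = "drop")
  outc_nested <- outc |> distinct(primaryid, outc_cod) |>
    group_by(primaryid) |> summarise(outcomes = list(outc_cod), .groups = "drop")

  cases <- demo |>
    mutate(age_years = age_to_years(age, age_cod),
           event_dt_precision = date_precision(event_dt)) |>
    left_join(drugs_nested, by = "primaryid") |>
    left_join(reac_nested, by = "primaryid") |>
    left_join(outc_nested, by = "primaryid") |>
    left_join(ther_start, by = "primaryid") |>
    mutate(n_drugs = coalesce(n_drugs, 0L),
           n_reactions = coalesce(n_reactions, 0L),
           outcomes = map(outcomes, ~ .x %||% character(0)))

  no_reac <- cases$n_reactions == 0
  if (any(no_reac)) {
    warn(sprintf("dropped %d case(s) with no reactions", sum(no_reac)))
  }
  cases <- cases[!no_reac, ]
  structure(
    cases |>
      select(caseid, primaryid, fda_dt, event_dt, event_dt_precision,
             age_years, sex, country = reporter_country, occp_cod, drugs,
             n_drugs, reactions, n_reactions, outcomes, therapy_start) |>
      arrange(caseid),
    n_dropped_no_reaction = sum(no_reac)
  )
}

#' Days from therapy start to event onset
#'
#' `event_dt - therapy_start` in days, per case. The difference is only
#' defined when both dates have day precision; negative differences (event
#' before therapy start) are excluded rather than clipped, and counted in
#' `attr(x, "n_negative_excluded")`.
#'
#' @param cases case table from [assemble_cases()].
#' @return the input with an `onset_days` column added (`NA` where
#'   undefined).
#' @export
onset_days <- function(cases) {
  event <- faers_date_as_date(cases$event_dt)
  start <- faers_date_as_date(cases$therapy_start)
  d <- as.integer(event - start)
  negative <- !is.na(d) & d < 0
  d[negative] <- NA_integer_
  structure(mutate(cases, onset_days = d),
            n_negative_excluded = sum(negative))
}

#' Export the audit case table
#'
#' Flat per-case TSV (caseid, primaryid, fda_dt, age_years, sex, country,
#' n_drugs, n_reactions, onset_days) for manual inspection of the claim
#' chain.
#'
#' @param cases case table (after [onset_days()] if onset is wanted).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_case_audit <- function(cases, path) {
  out <- cases
  if (!"onset_days" %in% names(out)) out$onset_days <- NA_integer_
  out |>
    select(caseid, primaryid, fda_dt, age_years, sex, country, n_drugs,
           n_reactions, onset_days) |>
    write_tsv(path, progress = FALSE)
  invisible(path)
}
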