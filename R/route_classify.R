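# Formulation (route-of-administration) labelling of target-drug cases.
#
# The identification rule uses four free-text drug fields in fixed
# precedence: explicit route, then dose form, then trade name, then dosing
# frequency. The first field that fires decides; a field whose values point
# at both formulations at once is a conflict and the case is left
# unclassified (surfaced, not guessed). Cases where no field fires are
# excluded from the formulation comparison.

ROUTE_FIELDS <- c("route", "dose_form", "drugname", "dose_freq")

#' Load a route-classification rulebook
#'
#' The rulebook is a YAML mapping `field -> label -> keyword list` (see
#' `system.file("extdata", "route_rules.yaml", package = "faersignal")` for
#' the packaged default). Keywords are matched as case-insensitive
#' substrings of the corresponding drug field.
#'
#' @param path YAML path; default is the packaged rulebook.
#' @return named list of class `route_rules`.
#' @export
read_route_rules <- function(path = system.file("extdata", "route_rules.yaml",
                                                package = "faersignal")) {
  rules <- yaml::read_yaml(path)
  missing_fields <- setdiff(ROUTE_FIELDS, names(rules))
  if (length(missing_fields) > 0) {
    stopf("rulebook is missing field(s): %s",
          paste(missing_fields, collapse = ", "),
          class = "faersignal_config_error")
  }
  structure(rules[ROUTE_FIELDS], class = c("route_rules", "list"))
}

#' Classify the formulation of each target-drug case
#'
#' Applies the rulebook to the target-drug rows (role `PS`, name matching
#' `target_patterns`) of each case. Fields are tried in the precedence
#' `route > dose_form > drugname > dose_freq`; the first field with a
#' keyword hit decides and is recorded as the evidence. If, at the deciding
#' precedence level, keywords for both formulations fire (across the case's
#' target rows), the case is `UNCLASSIFIED` with `conflict = TRUE`. Cases
#' where no rule fires are `UNCLASSIFIED` with `conflict = FALSE` and are
#' excluded from the route comparison.
#'
#' @param cases case table from [assemble_cases()] (needs the `drugs`
#'   list-column).
#' @param rules rulebook from [read_route_rules()].
#' @param target_patterns patterns identifying target-drug rows.
#' @return tibble `(caseid, label, evidence, conflict)` with `label` in
#'   `c("ORAL", "SUBCUTANEOUS", "UNCLASSIFIED")` and `evidence` the deciding
#'   field (`NA` when unclassified).
#' @export
classify_route <- function(cases, rules = read_route_rules(),
                           target_patterns = semaglutide_patterns()) {
  drug_long <- cases |>
    select(caseid, drugs) |>
    unnest(drugs, names_sep = NULL) |>
    filter(role_cod == "PS", matches_any_pattern(drugname, target_patterns))

  # per case and field: did any oral / any subcutaneous keyword fire?
  field_hits <- map(ROUTE_FIELDS, function(field) {
    values <- drug_long[[field]]
    tibble(caseid = drug_long$caseid,
           oral = matches_any_pattern(values, rules[[field]]$oral),
           subcutaneous = matches_any_pattern(values, rules[[field]]$subcutaneous)) |>
      group_by(caseid) |>
      summarise(oral = any(oral), subcutaneous = any(subcutaneous),
                .groups = "drop") |>
      mutate(field = field)
  }) |> list_rbind()

  decided <- field_hits |>
    filter(oral | subcutaneous) |>
    mutate(field = factor(field, levels = ROUTE_FIELDS)) |>
    group_by(caseid) |>
    arrange(field, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(label = case_when(oral & subcutaneous ~ "UNCLASSIFIED",
                             oral ~ "ORAL",
                             TRUE ~ "SUBCUTANEOUS"),
           conflict = oral & subcutaneous,
           evidence = ifelse(conflict, NA_character_, as.character(field))) |>
    select(caseid, label, evidence, conflict)

  tibble(caseid = cases$caseid) |>
    left_join(decided, by = "caseid") |>
    mutate(label = coalesce(label, "UNCLASSIFIED"),
           conflict = coalesce(conflict, FALSE)) |>
    arrange(caseid)
}

#' Partition cases into formulation cohorts
#'
#' @param cases case table.
#' @param labels label table from [classify_route()].
#' @return list with `oral` and `subcutaneous` case tables (disjoint,
#'   exhaustive over classified cases) and `n_excluded`, the number of
#'   unclassified cases left out of the comparison.
#' @export
split_cohorts <- function(cases, labels) {
  lab <- labels$label[match(cases$caseid, labels$caseid)]
  list(oral = cases[lab %in% "ORAL", ],
       subcutaneous = cases[lab %in% "SUBCUTANEOUS", ],
       n_excluded = sum(lab %in% "UNCLASSIFIED" | is.na(lab)))
}

#' Export route labels
#'
#' @param labels tibble from [classify_route()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_route_labels <- function(labels, path) {
  write_tsv(labels, path, progress = FALSE)
  invisible(path)
}
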