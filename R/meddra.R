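# PT -> SOC mapping and (case, PT) event construction.

#' Map case reactions to SOC-annotated events
#'
#' Expands each case's reaction set into one event per distinct
#' (case, PT) pair and annotates it with the System Organ Class from the
#' dictionary. Matching uses normalized keys (trimmed, whitespace-collapsed,
#' case-folded); duplicate PTs within one case collapse to a single event.
#' PTs absent from the dictionary are returned separately
#' (`attr(x, "unmapped")`), never silently dropped: they are data, not an
#' error.
#'
#' Works on any table with an id column and a PT list-column, so the same
#' operation serves FAERS cases (`caseid` + `reactions`) and coded reviews
#' (`review_id` + `pts`).
#'
#' @param data tibble with an id column and a list-column of PTs.
#' @param dictionary tibble from [read_pt_soc_dictionary()].
#' @param id_col,pts_col column names (defaults `"caseid"`, `"reactions"`).
#' @return tibble of events (`caseid`, `pt`, `soc`), one row per distinct
#'   mapped (case, PT); unmapped distinct PTs in `attr(x, "unmapped")`.
#' @export
map_events <- function(data, dictionary, id_col = "caseid",
                       pts_col = "reactions") {
  stopifnot(id_col %in% names(data), pts_col %in% names(data))
  long <- tibble(
    caseid = rep(data[[id_col]], lengths(data[[pts_col]])),
    pt = unlist(data[[pts_col]], use.names = FALSE) %||% character(0)
  ) |>
    mutate(pt = str_squish(pt), pt_key = pt_normalize(pt)) |>
    distinct(caseid, pt_key, .keep_all = TRUE)
  mapped <- long |>
    inner_join(select(dictionary, pt_key, soc), by = "pt_key") |>
    select(caseid, pt, soc) |>
    arrange(caseid, pt)
  unmapped <- long |>
    anti_join(dictionary, by = "pt_key") |>
    distinct(pt) |>
    pull(pt) |>
    sort()
  structure(mapped, unmapped = unmapped)
}

#' Export the event table
#'
#' @param events tibble from [map_events()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_event_table <- function(events, path) {
  write_tsv(as_tibble(events), path, progress = FALSE)
  invisible(path)
}
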