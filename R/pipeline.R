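# Pipeline orchestration: ingest -> dedup -> assemble -> map -> classify ->
# signals -> compare -> describe, with a machine-readable run manifest.
#
# Every intermediate artifact is a plain TSV with a header so each stage of
# the claim chain is independently inspectable; the manifest records the
# record count entering and leaving every stage plus a checksum per output
# file.

#' Build a validated pipeline configuration
#'
#' Either `input_dir` (a directory of FAERS-dialect tables) or
#' `simulate = TRUE` (with `sim` a [sim_config()]) must be given. All
#' referenced paths are checked at validation time, before any compute.
#'
#' @param input_dir directory with FAERS tables (ignored when simulating).
#' @param quarter_tag table file tag (default `"SIM"`).
#' @param simulate generate input with [simulate_reports()] instead of
#'   reading files.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param target_patterns target-drug name patterns.
#' @param dictionary path to the PT->SOC TSV (default: packaged mini
#'   dictionary).
#' @param rulebook path to the route rulebook YAML (default: packaged).
#' @param min_count minimum report count for signal evaluation.
#' @param serious_codes outcome codes counted as serious.
#' @param reviews optional coded-review CSV for the source comparison.
#' @param output_dir where outputs and the manifest are written.
#' @param seed integer seed (forwarded to the simulator).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL,
                       quarter_tag = "SIM",
                       simulate = is.null(input_dir),
                       sim = sim_config(seed = seed),
                       target_patterns = semaglutide_patterns(),
                       dictionary = system.file("extdata", "pt_soc_mini.tsv",
                                                package = "faersignal"),
                       rulebook = system.file("extdata", "route_rules.yaml",
                                              package = "faersignal"),
                       min_count = 3,
                       serious_codes = c("DE", "LT", "HO", "DS", "CA", "RI"),
                       reviews = NULL,
                       output_dir = tempfile("faersignal_run_"),
                       seed = 1L) {
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stopf("input_dir '%s' does not exist", input_dir %||% "<missing>",
            class = "faersignal_config_error")
    }
  }
  for (p in c(dictionary, rulebook, reviews)) {
    if (!is.null(p) && (!nzchar(p) || !file.exists(p))) {
      stopf("configuration path '%s' does not exist", p,
            class = "faersignal_config_error")
    }
  }
  if (length(target_patterns) == 0) {
    stopf("target_patterns must be non-empty",
          class = "faersignal_config_error")
  }
  structure(list(input_dir = input_dir, quarter_tag = quarter_tag,
                 simulate = simulate, sim = sim,
                 target_patterns = target_patterns, dictionary = dictionary,
                 rulebook = rulebook, min_count = min_count,
                 serious_codes = serious_codes, reviews = reviews,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# The in-memory claim chain shared by run_pipeline() and the subcommands.
# Returns every intermediate object; writes nothing.
pipeline_core <- function(tables, config) {
  counts <- list(reports_read = nrow(tables$demo))

  log_stage("dedup", "deduplicating %d report versions", nrow(tables$demo))
  kept <- deduplicate_reports(tables$demo)
  counts$unique_cases <- nrow(kept)
  counts$duplicates_removed <- counts$reports_read - counts$unique_cases

  log_stage("assemble", "selecting target cases")
  target_ids <- select_target_cases(tables$drug, kept, config$target_patterns)
  cases <- assemble_cases(tables, kept, target_patterns = config$target_patterns)
  counts$cases_dropped_no_reaction <- attr(cases, "n_dropped_no_reaction")
  cases <- onset_days(cases)
  counts$negative_onsets_excluded <- attr(cases, "n_negative_excluded")
  target_cases <- filter(cases, caseid %in% target_ids)
  background_cases <- filter(cases, !caseid %in% target_ids)
  counts$target_cases <- nrow(target_cases)
  counts$background_cases <- nrow(background_cases)

  log_stage("map", "mapping PTs against %s", basename(config$dictionary))
  dictionary <- read_pt_soc_dictionary(config$dictionary)
  events <- map_events(cases, dictionary)
  counts$events_mapped <- nrow(events)
  counts$unmapped_pts <- length(attr(events, "unmapped"))

  log_stage("classify", "classifying formulation of %d target cases",
            nrow(target_cases))
  rules <- read_route_rules(config$rulebook)
  labels <- classify_route(target_cases, rules, config$target_patterns)
  cohorts <- split_cohorts(target_cases, labels)
  counts$oral_cases <- nrow(cohorts$oral)
  counts$subcutaneous_cases <- nrow(cohorts$subcutaneous)
  counts$excluded_unclassified <- cohorts$n_excluded

  log_stage("signals", "testing PTs, target vs background")
  signals <- detect_signals(events, target_cases$caseid,
                            background_cases$caseid, level = "pt",
                            min_count = config$min_count)
  counts$terms_tested <- attr(signals, "n_terms_tested")
  counts$signals_found <- sum(signals$is_signal)

  log_stage("compare", "formulation-unique PT signals")
  unique_sig <- unique_pt_signals(events, cohorts$oral$caseid,
                                  cohorts$subcutaneous$caseid,
                                  background_cases$caseid,
                                  min_count = config$min_count)
  gi <- route_vs_route_ror(events, "Gastrointestinal disorders",
                           cohorts$oral$caseid, cohorts$subcutaneous$caseid,
                           level = "soc", min_count = config$min_count)

  log_stage("describe", "descriptive tables")
  target_events <- filter(events, caseid %in% target_cases$caseid)
  describe <- list(
    demographics = demographics_table(target_cases),
    soc = soc_frequency_table(target_events),
    pt = pt_frequency_table(target_events),
    serious = list(
      oral = serious_outcome_rate(cohorts$oral, config$serious_codes),
      subcutaneous = serious_outcome_rate(cohorts$subcutaneous,
                                          config$serious_codes)
    ),
    onset = list(
      oral = onset_summary(cohorts$oral),
      subcutaneous = onset_summary(cohorts$subcutaneous)
    )
  )
  if (!is.null(config$reviews)) {
    reviews <- read_coded_reviews(config$reviews)
    review_events <- map_events(reviews, dictionary, id_col = "review_id",
                                pts_col = "pts")
    describe$review_demographics <- review_demographics_table(reviews)
    describe$review_soc <- soc_frequency_table(review_events)
    describe$soc_comparison <- compare_sources(describe$soc,
                                               describe$review_soc)
  }

  list(tables = tables, kept = kept, cases = cases,
       target_cases = target_cases, background_cases = background_cases,
       events = events, labels = labels, cohorts = cohorts,
       signals = signals, unique_signals = unique_sig, gi_route_ror = gi,
       describe = describe, counts = counts)
}

#' Run the full pipeline and write the output bundle
#'
#' Stages run in the order ingest, dedup, assemble, map, classify, signals,
#' compare, describe. Every output table is written as TSV with an MD5
#' checksum recorded in the manifest (`manifest.yaml`), together with the
#' resolved configuration and the record counts at each stage, so two runs
#' can be compared file by file. Under a fixed seed and configuration the
#' run is fully deterministic.
#'
#' @param config a [run_config()].
#' @return invisibly, the [pipeline_core()] result list plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$simulate) {
    log_stage("ingest", "simulating reports (seed %d)", config$sim$seed)
    sim <- simulate_reports(config$sim)
    tables <- sim$tables
  } else {
    log_stage("ingest", "reading quarter %s from %s", config$quarter_tag,
              config$input_dir)
    sim <- NULL
    tables <- read_quarter(config$input_dir, config$quarter_tag)
  }

  res <- pipeline_core(tables, config)
  out <- config$output_dir

  write_case_audit(res$cases, file.path(out, "cases.tsv"))
  write_event_table(res$events, file.path(out, "events.tsv"))
  write_route_labels(res$labels, file.path(out, "route_labels.tsv"))
  write_signal_table(res$signals, file.path(out, "signals_pt.tsv"))
  write_forest_table(res$signals, file.path(out, "forest_pt.tsv"))
  write_signal_table(res$unique_signals$oral,
                     file.path(out, "signals_unique_oral.tsv"))
  write_signal_table(res$unique_signals$subcutaneous,
                     file.path(out, "signals_unique_subcutaneous.tsv"))
  write_tsv(tidy(res$unique_signals$partition),
            file.path(out, "venn_partition.tsv"), progress = FALSE)
  write_tsv(res$gi_route_ror, file.path(out, "gi_route_vs_route.tsv"),
            progress = FALSE)
  write_freq_table(res$describe$demographics,
                   file.path(out, "demographics.tsv"))
  write_freq_table(res$describe$soc, file.path(out, "soc_frequency.tsv"))
  write_freq_table(res$describe$pt, file.path(out, "pt_frequency.tsv"))
  write_tsv(bind_rows(oral = res$describe$onset$oral,
                      subcutaneous = res$describe$onset$subcutaneous,
                      .id = "cohort"),
            file.path(out, "onset_summary.tsv"), progress = FALSE)
  write_tsv(bind_rows(oral = as_tibble(res$describe$serious$oral),
                      subcutaneous = as_tibble(res$describe$serious$subcutaneous),
                      .id = "cohort"),
            file.path(out, "serious_outcomes.tsv"), progress = FALSE)
  if (!is.null(res$describe$soc_comparison)) {
    write_csv(res$describe$soc_comparison,
              file.path(out, "soc_source_comparison.csv"), progress = FALSE)
  }

  files <- list.files(out, pattern = "\\.(tsv|csv)$", full.names = TRUE)
  manifest <- list(
    config = serialize_config(config),
    counts = res$counts,
    venn = list(unique_oral = length(res$unique_signals$partition$unique_left),
                shared = length(res$unique_signals$partition$shared),
                unique_subcutaneous =
                  length(res$unique_signals$partition$unique_right)),
    outputs = setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  log_stage("done", "outputs in %s", out)
  invisible(c(res, list(manifest = manifest, sim = sim)))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- if (config$simulate) {
    s <- unclass(config$sim)
    s$pt_catalog <- as.data.frame(s$pt_catalog)
    s$route_mix <- as.list(s$route_mix)
    s$missingness <- as.list(s$missingness)
    s$serious_outcome_prob <- as.list(s$serious_outcome_prob)
    s
  } else NULL
  cfg
}

# ---------------------------------------------------------------------------
# Command-line interface. `faers_cli()` is the dispatcher behind the thin
# Rscript wrapper in inst/cli/; it returns an exit status (0 ok, 2 config
# error, 3 data error) instead of quitting so it can be tested in-process.

CLI_USAGE <- "usage: faersignal <subcommand> [--key value ...]

subcommands:
  simulate   --out DIR [--seed N] [--n-target N] [--n-background N]
             [--duplicate-fraction F] [--reviews N]
  ingest     --in DIR --out DIR [--tag TAG]
  signals    --in DIR --out DIR [--tag TAG] [--dictionary TSV] [--min-count N]
  compare    --in DIR --out DIR [--tag TAG] [--dictionary TSV]
             [--rulebook YAML] [--min-count N]
  describe   --in DIR --out DIR [--tag TAG] [--dictionary TSV]
             [--reviews CSV]
  run-all    (--in DIR | --simulate) --out DIR [--tag TAG] [--seed N]
             [--dictionary TSV] [--rulebook YAML] [--min-count N]
             [--reviews CSV]

Any subcommand accepts --help."

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) {
      stopf("unexpected argument '%s'", key, class = "faersignal_config_error")
    }
    key <- substring(key, 3)
    if (key %in% c("help", "simulate")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i == length(args)) {
        stopf("missing value for --%s", key, class = "faersignal_config_error")
      }
      opts[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  opts
}

cli_run_config <- function(opts) {
  run_config(
    input_dir = opts[["in"]],
    quarter_tag = opts[["tag"]] %||% "SIM",
    simulate = isTRUE(opts[["simulate"]]) || is.null(opts[["in"]]),
    sim = sim_config(seed = as.integer(opts[["seed"]] %||% 1L)),
    dictionary = opts[["dictionary"]] %||%
      system.file("extdata", "pt_soc_mini.tsv", package = "faersignal"),
    rulebook = opts[["rulebook"]] %||%
      system.file("extdata", "route_rules.yaml", package = "faersignal"),
    min_count = as.numeric(opts[["min-count"]] %||% 3),
    reviews = opts[["reviews"]],
    output_dir = opts[["out"]] %||% tempfile("faersignal_run_"),
    seed = as.integer(opts[["seed"]] %||% 1L)
  )
}

#' Command-line entry point
#'
#' Dispatches the subcommands (`simulate`, `ingest`, `signals`, `compare`,
#' `describe`, `run-all`) documented in the package CLI. Returns an exit
#' status rather than quitting: 0 on success, 2 on configuration errors,
#' 3 on data errors.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly.
#' @export
faers_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[[1]] %in% c("--help", "-h", "help")) {
    cat(CLI_USAGE, "\n")
    return(invisible(0L))
  }
  sub <- args[[1]]
  rest <- args[-1]
  status <- tryCatch({
    opts <- parse_cli_args(rest)
    if (isTRUE(opts$help)) {
      cat(CLI_USAGE, "\n")
      return(invisible(0L))
    }
    switch(sub,
      "simulate" = cli_simulate(opts),
      "ingest" = , "signals" = , "compare" = , "describe" = ,
      "run-all" = cli_stage_run(sub, opts),
      stopf("unknown subcommand '%s'", sub,
            class = "faersignal_config_error")
    )
    0L
  },
  faersignal_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("data error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}

cli_simulate <- function(opts) {
  out <- opts[["out"]] %||% stopf("simulate requires --out",
                                  class = "faersignal_config_error")
  cfg <- sim_config(
    n_cases_target = as.integer(opts[["n-target"]] %||% 5000L),
    n_cases_background = as.integer(opts[["n-background"]] %||% 5000L),
    duplicate_fraction = as.numeric(opts[["duplicate-fraction"]] %||% 0.1),
    seed = as.integer(opts[["seed"]] %||% 1L)
  )
  sim <- simulate_reports(cfg)
  write_simulation(sim, out, opts[["tag"]] %||% "SIM")
  reviews <- simulate_coded_reviews(cfg,
                                    n_reviews = as.integer(opts[["reviews"]] %||% 422L))
  write_coded_reviews(reviews, file.path(out, "coded_reviews.csv"))
  log_stage("simulate", "wrote %s", out)
}

cli_stage_run <- function(sub, opts) {
  if (sub != "run-all" && is.null(opts[["in"]])) {
    stopf("%s requires --in", sub, class = "faersignal_config_error")
  }
  config <- cli_run_config(opts)
  res <- run_pipeline(config)
  invisible(res)
}
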