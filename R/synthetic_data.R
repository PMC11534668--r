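# Synthetic FAERS-like report generator with known ground truth.
#
# Every embedded quantity the pipeline later estimates is controlled here:
# per-PT reporting odds ratios, the duplicate fraction, the route mix, the
# onset distribution and the serious-outcome probabilities. The generator
# emits the exact table dialect faers_io reads, so the full claim chain can
# be validated end to end against ground truth.

#' Default PT catalog for the synthetic generator
#'
#' A catalog of MedDRA-style Preferred Terms with their System Organ Class
#' and an embedded reporting odds ratio for the target drug. The defaults
#' emulate the gastrointestinal-dominated profile of a GLP-1 receptor
#' agonist: elevated odds for nausea, vomiting, diarrhoea and related terms,
#' null odds (ROR = 1) for unrelated background terms.
#'
#' @return tibble with columns `pt`, `soc`, `ror`.
#' @export
default_pt_catalog <- function() {
  tribble(
    ~pt,                    ~soc,                                                   ~ror,
    "Nausea",               "Gastrointestinal disorders",                           5,
    "Vomiting",             "Gastrointestinal disorders",                           4,
    "Diarrhoea",            "Gastrointestinal disorders",                           3.5,
    "Constipation",         "Gastrointestinal disorders",                           2.5,
    "Abdominal pain upper", "Gastrointestinal disorders",                           2,
    "Abdominal distension", "Gastrointestinal disorders",                           2,
    "Eructation",           "Gastrointestinal disorders",                           3,
    "Pancreatitis",         "Gastrointestinal disorders",                           2,
    "Decreased appetite",   "Metabolism and nutrition disorders",                   3,
    "Dehydration",          "Metabolism and nutrition disorders",                   1.5,
    "Weight decreased",     "Investigations",                                       3,
    "Blood glucose increased", "Investigations",                                    1.5,
    "Headache",             "Nervous system disorders",                             1,
    "Dizziness",            "Nervous system disorders",                             1.2,
    "Fatigue",              "General disorders and administration site conditions", 1.2,
    "Malaise",              "General disorders and administration site conditions", 1,
    "Vision blurred",       "Eye disorders",                                        1,
    "Rash",                 "Skin and subcutaneous tissue disorders",               1,
    "Insomnia",             "Psychiatric disorders",                                1,
    "Back pain",            "Musculoskeletal and connective tissue disorders",      1
  )
}

#' Build a validated synthetic-data configuration
#'
#' @param n_cases_target number of target-drug cases.
#' @param n_cases_background number of background (other-drug) cases.
#' @param duplicate_fraction proportion of cases emitted as multiple report
#'   versions sharing a `caseid` (distinct, increasing `primaryid`s and
#'   non-decreasing `fda_dt`).
#' @param pt_catalog tibble (`pt`, `soc`, `ror`) of reaction terms and their
#'   embedded reporting odds ratio (all `ror >= 0`).
#' @param p_background per-PT occurrence probability in the background arm.
#'   The target-arm probability is derived from the embedded ROR on the odds
#'   scale, so the population reporting odds ratio is exact:
#'   `odds_t = ror * p_b / (1 - p_b)`, `p_t = odds_t / (1 + odds_t)`.
#' @param route_mix named proportions over
#'   `c(oral, subcutaneous, unclassifiable)`; must sum to 1.
#' @param onset list with `meanlog`, `sdlog` of the log-normal days-to-onset
#'   distribution (rounded to integer days). The default has median 4 and
#'   upper quartile 32 days.
#' @param missingness named per-field missing probabilities (`age`, `sex`,
#'   `reporter_country`, `event_dt`, `start_dt`, `route`, `dose_form`,
#'   `dose_freq`).
#' @param trade_name_prob probability that a target-drug row carries the
#'   formulation trade name rather than the plain substance name.
#' @param female_prob probability of sex `F` when sex is recorded.
#' @param serious_outcome_prob named per-case probability of each FAERS
#'   outcome code (`DE`, `LT`, `HO`, `DS`, `CA`, `RI`, `OT`).
#' @param duplicate_noise if `TRUE`, later report versions may fill in
#'   missing demographics; by default duplicates differ only in `primaryid`
#'   and `fda_dt`, which isolates the deduplication contract.
#' @param seed integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases_target = 5000,
                       n_cases_background = 5000,
                       duplicate_fraction = 0.1,
                       pt_catalog = default_pt_catalog(),
                       p_background = 0.01,
                       route_mix = c(oral = 0.13, subcutaneous = 0.85,
                                     unclassifiable = 0.02),
                       onset = list(meanlog = log(4),
                                    sdlog = log(8) / stats::qnorm(0.75)),
                       missingness = c(age = 0.466, sex = 0.04,
                                       reporter_country = 0.02,
                                       event_dt = 0.25, start_dt = 0.25,
                                       route = 0.3, dose_form = 0.4,
                                       dose_freq = 0.5),
                       trade_name_prob = 0.8,
                       female_prob = 0.62,
                       serious_outcome_prob = c(DE = 0.005, LT = 0.004,
                                                HO = 0.02, DS = 0.003,
                                                CA = 0.0005, RI = 0.002,
                                                OT = 0.12),
                       duplicate_noise = FALSE,
                       seed = 1L) {
  stopifnot(n_cases_target >= 0, n_cases_background >= 0,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            all(c("pt", "soc", "ror") %in% names(pt_catalog)),
            p_background > 0, p_background < 1,
            trade_name_prob >= 0, trade_name_prob <= 1,
            female_prob >= 0, female_prob <= 1,
            all(missingness >= 0), all(missingness <= 1),
            all(serious_outcome_prob >= 0), all(serious_outcome_prob <= 1))
  if (any(pt_catalog$ror < 0)) {
    stopf("embedded ROR must be >= 0 (offending PT: %s)",
          paste(pt_catalog$pt[pt_catalog$ror < 0], collapse = ", "),
          class = "faersignal_config_error")
  }
  if (anyDuplicated(pt_normalize(pt_catalog$pt)) > 0) {
    stopf("pt_catalog contains duplicate PTs", class = "faersignal_config_error")
  }
  route_mix <- route_mix[c("oral", "subcutaneous", "unclassifiable")]
  if (anyNA(route_mix) || abs(sum(route_mix) - 1) > 1e-8) {
    stopf("route_mix must be named proportions over oral/subcutaneous/unclassifiable summing to 1",
          class = "faersignal_config_error")
  }
  odds_b <- p_background / (1 - p_background)
  odds_t <- pt_catalog$ror * odds_b
  p_target <- odds_t / (1 + odds_t)
  bad <- !is.finite(p_target) | p_target >= 1
  if (any(bad)) {
    stopf("infeasible target-arm probability for PT(s): %s",
          paste(pt_catalog$pt[bad], collapse = ", "),
          class = "faersignal_config_error")
  }
  structure(list(
    n_cases_target = as.integer(n_cases_target),
    n_cases_background = as.integer(n_cases_background),
    duplicate_fraction = duplicate_fraction,
    pt_catalog = as_tibble(pt_catalog) |>
      mutate(p_target = p_target, p_background = p_background),
    p_background = p_background,
    route_mix = route_mix,
    onset = onset,
    missingness = missingness,
    trade_name_prob = trade_name_prob,
    female_prob = female_prob,
    serious_outcome_prob = serious_outcome_prob,
    duplicate_noise = duplicate_noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

TARGET_DRUG_POOL <- list(
  oral = c("RYBELSUS", "RYBELSUS (SEMAGLUTIDE)"),
  subcutaneous = c("OZEMPIC", "WEGOVY", "OZEMPIC (SEMAGLUTIDE)",
                   "WEGOVY (SEMAGLUTIDE)")
)

BACKGROUND_DRUG_POOL <- c(
  "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "INSULIN GLARGINE",
  "DULAGLUTIDE", "SITAGLIPTIN", "EMPAGLIFLOZIN", "SERTRALINE",
  "OMEPRAZOLE", "IBUPROFEN"
)

FILLER_PT <- "Drug ineffective"

rand_date_int <- function(n, from = "2018-01-01", to = "2023-06-30") {
  d <- as.Date(from) + floor(runif(n) * (as.numeric(as.Date(to) - as.Date(from)) + 1))
  as.integer(format(d, "%Y%m%d"))
}

date_plus_days <- function(x, days) {
  d <- faers_date_as_date(x) + days
  as.integer(format(d, "%Y%m%d"))
}

degrade_precision <- function(x, to) {
  out <- x
  out[to == "month"] <- x[to == "month"] %/% 100L
  out[to == "year"] <- x[to == "year"] %/% 10000L
  out
}

maybe_missing <- function(x, prob) {
  x[runif(length(x)) < prob] <- NA
  x
}

#' Simulate FAERS-style report tables with known ground truth
#'
#' Generates the five quarterly tables (`demo`, `drug`, `reac`, `outc`,
#' `ther`) for a target-drug arm and a background arm. For every catalog PT
#' with embedded odds ratio `r`, the per-arm occurrence probabilities are
#' set so the population reporting odds ratio equals `r` exactly (odds-scale
#' parameterization, background probability held fixed). Each case has at
#' least one drug (target cases carry the target drug with role `PS`) and
#' at least one reaction (cases drawing no catalog PT receive the filler
#' term `"Drug ineffective"`, which is not part of the catalog and so does
#' not disturb the embedded odds). A configurable fraction of cases is
#' emitted as multiple report versions so deduplication can be tested
#' against an exact ground-truth case count.
#'
#' @param config a [sim_config()] object.
#' @return list of class `faers_simulation` with elements
#'   * `tables`: named list of the five tibbles (class `faers_tables`),
#'   * `truth`: list with `cases` (caseid, arm, route, onset_days, selected
#'     primaryid), `pt_probs` (pt, ror, p_target, p_background) and
#'     `n_cases`,
#'   * `config`: the resolved configuration.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(config) {
  n_t <- config$n_cases_target
  n_b <- config$n_cases_background
  n <- n_t + n_b
  caseid <- as.character(10000000L + seq_len(n))
  arm <- rep(c("target", "background"), c(n_t, n_b))

  route <- rep(NA_character_, n)
  if (n_t > 0) {
    route[seq_len(n_t)] <- sample(names(config$route_mix), n_t, replace = TRUE,
                                  prob = config$route_mix)
  }

  # demographics ------------------------------------------------------------
  miss <- config$missingness
  age_years <- pmin(pmax(round(stats::rnorm(n, mean = 61, sd = 14)), 18), 95)
  age_cod <- rep("YR", n)
  dec <- runif(n) < 0.05 & age_years %% 10 == 0  # some ages reported in decades
  age <- ifelse(dec, age_years / 10, age_years)
  age_cod[dec] <- "DEC"
  age <- maybe_missing(age, miss[["age"]])
  age_cod[is.na(age)] <- NA
  sex <- maybe_missing(ifelse(runif(n) < config$female_prob, "F", "M"),
                       miss[["sex"]])
  country <- maybe_missing(
    sample(c("US", "GB", "CA", "JP", "FR", "BR", "DK", "AU", "IL", "SE"), n,
           replace = TRUE,
           prob = c(0.86, 0.027, 0.026, 0.025, 0.013, 0.012, 0.012, 0.011,
                    0.007, 0.007)),
    miss[["reporter_country"]])
  occp <- sample(c("MD", "PH", "HP", "CN", "LW", "OT"), n, replace = TRUE,
                 prob = c(0.38, 0.20, 0.19, 0.2224, 0.002, 0.0056))

  # therapy start, onset, event and received dates --------------------------
  start_full <- rand_date_int(n, to = "2023-03-31")
  onset_days <- pmax(round(rlnorm(n, config$onset$meanlog, config$onset$sdlog)), 0)
  event_full <- date_plus_days(start_full, onset_days)
  fda_dt <- date_plus_days(event_full, sample(0:90, n, replace = TRUE))

  event_prec <- sample(c("day", "month", "year"), n, replace = TRUE,
                       prob = c(0.90, 0.08, 0.02))
  event_dt <- maybe_missing(degrade_precision(event_full, event_prec),
                            miss[["event_dt"]])
  start_prec <- sample(c("day", "month"), n, replace = TRUE, prob = c(0.92, 0.08))
  start_dt <- maybe_missing(degrade_precision(start_full, start_prec),
                            miss[["start_dt"]])

  demo <- tibble(
    primaryid = paste0(caseid, "1"), caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
    reporter_country = country, occp_cod = occp
  )

  # reactions ---------------------------------------------------------------
  cat <- config$pt_catalog
  is_target <- arm == "target"
  reac_idx <- vector("list", nrow(cat))
  for (k in seq_len(nrow(cat))) {
    p <- ifelse(is_target, cat$p_target[[k]], cat$p_background[[k]])
    reac_idx[[k]] <- which(runif(n) < p)
  }
  reac <- tibble(
    primaryid = paste0(caseid[unlist(reac_idx)], "1"),
    pt = rep(cat$pt, lengths(reac_idx))
  )
  with_pt <- unique(unlist(reac_idx))
  fillers <- setdiff(seq_len(n), with_pt)
  if (length(fillers) > 0) {
    reac <- bind_rows(reac, tibble(primaryid = paste0(caseid[fillers], "1"),
                                   pt = FILLER_PT))
  }
  reac <- arrange(reac, primaryid, pt)

  # outcomes ----------------------------------------------------------------
  outc_rows <- map(names(config$serious_outcome_prob), function(code) {
    idx <- which(runif(n) < config$serious_outcome_prob[[code]])
    tibble(primaryid = paste0(caseid[idx], "1"), outc_cod = code)
  })
  outc <- arrange(list_rbind(outc_rows), primaryid, outc_cod)

  # drugs -------------------------------------------------------------------
  drug1 <- tibble(primaryid = paste0(caseid, "1"), drug_seq = 1L,
                  role_cod = "PS", drugname = NA_character_,
                  route = NA_character_, dose_form = NA_character_,
                  dose_freq = NA_character_)
  oral <- which(route %in% "oral")
  subq <- which(route %in% "subcutaneous")
  uncl <- which(route %in% "unclassifiable")
  bg <- which(!is_target)
  trade <- runif(n) < config$trade_name_prob
  drug1$drugname[oral] <- ifelse(trade[oral],
                                 sample(TARGET_DRUG_POOL$oral, length(oral), TRUE),
                                 "SEMAGLUTIDE")
  drug1$drugname[subq] <- ifelse(trade[subq],
                                 sample(TARGET_DRUG_POOL$subcutaneous, length(subq), TRUE),
                                 "SEMAGLUTIDE")
  drug1$drugname[uncl] <- "SEMAGLUTIDE"
  drug1$drugname[bg] <- sample(BACKGROUND_DRUG_POOL, length(bg), TRUE)
  drug1$route[oral] <- maybe_missing(rep("ORAL", length(oral)), miss[["route"]])
  drug1$route[subq] <- maybe_missing(
    sample(c("SUBCUTANEOUS", "SUBCUT"), length(subq), TRUE), miss[["route"]])
  drug1$dose_form[oral] <- maybe_missing(rep("TABLET", length(oral)),
                                         miss[["dose_form"]])
  drug1$dose_form[subq] <- maybe_missing(
    sample(c("SOLUTION FOR INJECTION", "INJECTION", "PEN"), length(subq), TRUE),
    miss[["dose_form"]])
  drug1$dose_freq[oral] <- maybe_missing(
    sample(c("QD", "DAILY"), length(oral), TRUE), miss[["dose_freq"]])
  drug1$dose_freq[subq] <- maybe_missing(
    sample(c("QW", "WEEKLY"), length(subq), TRUE), miss[["dose_freq"]])

  n_conmed <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  con_case <- rep(seq_len(n), n_conmed)
  conmeds <- tibble(
    primaryid = paste0(caseid[con_case], "1"),
    drug_seq = unlist(lapply(n_conmed[n_conmed > 0], function(k) 1L + seq_len(k))),
    role_cod = sample(c("C", "SS", "I"), length(con_case), TRUE,
                      prob = c(0.8, 0.15, 0.05)),
    drugname = sample(BACKGROUND_DRUG_POOL, length(con_case), TRUE),
    route = NA_character_, dose_form = NA_character_, dose_freq = NA_character_
  )
  drug <- arrange(bind_rows(drug1, conmeds), primaryid, drug_seq)

  # therapy -----------------------------------------------------------------
  ther <- tibble(
    primaryid = paste0(caseid, "1"), dsg_drug_seq = 1L, start_dt = start_dt,
    end_dt = maybe_missing(date_plus_days(start_full,
                                          onset_days + sample(0:60, n, TRUE)),
                           0.5)
  )

  # duplicate report versions ----------------------------------------------
  n_dup <- round(config$duplicate_fraction * n)
  dup_cases <- if (n_dup > 0) sort(sample(seq_len(n), n_dup)) else integer(0)
  selected_pid <- paste0(caseid, "1")
  if (length(dup_cases) > 0) {
    n_versions <- sample(2:3, length(dup_cases), replace = TRUE,
                         prob = c(0.7, 0.3))
    extra <- map2(dup_cases, n_versions, function(i, v) {
      tibble(case = i, version = 2:v)
    }) |> list_rbind()
    extra$primaryid <- paste0(caseid[extra$case], extra$version)
    extra$fda_dt <- date_plus_days(fda_dt[extra$case],
                                   cumsum_by(sample(0:180, nrow(extra), TRUE),
                                             extra$case))
    selected_pid[dup_cases] <- paste0(caseid[dup_cases], n_versions)

    version_map <- tibble(primaryid = paste0(caseid[extra$case], "1"),
                          .new_primaryid = extra$primaryid,
                          .new_fda_dt = extra$fda_dt)
    dup_row <- function(tbl) {
      out <- inner_join(tbl, version_map, by = "primaryid",
                        relationship = "many-to-many")
      out$primaryid <- out$.new_primaryid
      select(out, -".new_primaryid", -".new_fda_dt")
    }
    demo_extra <- inner_join(demo, version_map, by = "primaryid")
    demo_extra$primaryid <- demo_extra$.new_primaryid
    demo_extra$fda_dt <- demo_extra$.new_fda_dt
    demo_extra <- select(demo_extra, -".new_primaryid", -".new_fda_dt")
    if (config$duplicate_noise) {
      fill_age <- is.na(demo_extra$age) & runif(nrow(demo_extra)) < 0.5
      demo_extra$age[fill_age] <- 60
      demo_extra$age_cod[fill_age] <- "YR"
    }
    demo <- bind_rows(demo, demo_extra)
    drug <- bind_rows(drug, dup_row(drug))
    reac <- bind_rows(reac, dup_row(reac))
    outc <- bind_rows(outc, dup_row(outc))
    ther <- bind_rows(ther, dup_row(ther))
  }

  tables <- structure(list(demo = arrange(demo, caseid, primaryid),
                           drug = arrange(drug, primaryid, drug_seq),
                           reac = arrange(reac, primaryid, pt),
                           outc = arrange(outc, primaryid, outc_cod),
                           ther = arrange(ther, primaryid, dsg_drug_seq)),
                      class = c("faers_tables", "list"))
  truth_cases <- tibble(caseid = caseid, arm = arm, route = route,
                        onset_days = onset_days,
                        selected_primaryid = selected_pid)
  structure(list(
    tables = tables,
    truth = list(cases = truth_cases,
                 pt_probs = select(cat, pt, ror, p_target, p_background),
                 n_cases = n),
    config = config
  ), class = "faers_simulation")
}

# per-group cumulative sum (groups are contiguous run ids)
cumsum_by <- function(x, group) {
  unlist(lapply(split(x, group), cumsum), use.names = FALSE)
}

#' Simulate coded social-media reviews
#'
#' Emulates a manually MedDRA-coded patient-review table: each review
#' carries one to five PTs drawn without replacement from the catalog,
#' weighted by the target-arm occurrence profile (so gastrointestinal terms
#' dominate under the default catalog), plus demographics drawn from the
#' same configuration.
#'
#' @param config a [sim_config()] object (the PT catalog, `female_prob` and
#'   age model are used).
#' @param n_reviews number of reviews to generate.
#' @param seed integer seed; defaults to `config$seed + 1` so reviews are
#'   decoupled from the report stream.
#' @return tibble with columns `review_id`, `date`, `age`, `sex`, `pts`
#'   (list-column), compatible with [write_coded_reviews()].
#' @export
simulate_coded_reviews <- function(config, n_reviews = 422,
                                   seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), nrow(config$pt_catalog) > 0)
  with_seed(seed, {
    cat <- config$pt_catalog
    n_pts <- sample(1:5, n_reviews, replace = TRUE,
                    prob = c(0.35, 0.30, 0.20, 0.10, 0.05))
    n_pts <- pmin(n_pts, nrow(cat))
    pts <- map(n_pts, function(k) {
      sample(cat$pt, k, prob = cat$p_target)
    })
    tibble(
      review_id = sprintf("R%06d", seq_len(n_reviews)),
      date = format(as.Date("2018-01-01") +
                      floor(runif(n_reviews) * 2027), "%Y-%m-%d"),
      age = maybe_missing(pmin(pmax(round(stats::rnorm(n_reviews, 52, 12)), 18), 90),
                          0.05),
      sex = ifelse(runif(n_reviews) < config$female_prob, "F", "M"),
      pts = pts
    )
  })
}

#' Write a simulation to disk
#'
#' Emits the five quarterly tables in the FAERS dialect, a YAML copy of the
#' resolved configuration, and a ground-truth TSV (`pt`, `ror`, `p_target`,
#' `p_background`) so a file-mediated pipeline run can be checked against
#' the embedded parameters.
#'
#' @param sim a [simulate_reports()] result.
#' @param directory output directory.
#' @param quarter_tag tag for the table file names (default `"SIM"`).
#' @return invisibly, the output directory.
#' @export
write_simulation <- function(sim, directory, quarter_tag = "SIM") {
  stopifnot(inherits(sim, "faers_simulation"))
  write_quarter(sim$tables, directory, quarter_tag)
  cfg <- sim$config
  cfg$pt_catalog <- as.data.frame(cfg$pt_catalog)
  yaml::write_yaml(unclass(cfg), file.path(directory, "sim_config.yaml"))
  write_tsv(sim$truth$pt_probs, file.path(directory, "ground_truth_pt.tsv"),
            progress = FALSE)
  write_tsv(sim$truth$cases, file.path(directory, "ground_truth_cases.tsv"),
            progress = FALSE)
  invisible(directory)
}
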