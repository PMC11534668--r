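# Tiny hand-written fixtures used across the suite. Built in code so every
# expected value can be verified by eye.

tiny_demo <- function() {
  tibble::tribble(
    ~primaryid, ~caseid, ~fda_dt,   ~event_dt, ~age, ~age_cod, ~sex, ~reporter_country, ~occp_cod,
    "11",       "1",     20220110L, 20220105L, 62,   "YR",     "F",  "US",              "MD",
    "21",       "2",     20220215L, 202202L,   6,    "DEC",    "M",  "US",              "CN",
    "31",       "3",     20230301L, 20230310L, 45,   "YR",     "F",  "GB",              "HP"
  )
}

tiny_drug <- function() {
  tibble::tribble(
    ~primaryid, ~drug_seq, ~role_cod, ~drugname,              ~route,         ~dose_form, ~dose_freq,
    "11",       1L,        "PS",      "OZEMPIC (SEMAGLUTIDE)", "SUBCUTANEOUS", NA,         "QW",
    "11",       2L,        "C",       "METFORMIN",             NA,             NA,         NA,
    "21",       1L,        "PS",      "RYBELSUS",              NA,             NA,         NA,
    "31",       1L,        "PS",      "METFORMIN",             "ORAL",         "TABLET",   "QD",
    "31",       2L,        "C",       "SEMAGLUTIDE",           NA,             NA,         NA
  )
}

tiny_reac <- function() {
  tibble::tribble(
    ~primaryid, ~pt,
    "11",       "Nausea",
    "11",       "Vomiting",
    "21",       "Nausea",
    "31",       "Headache"
  )
}

tiny_outc <- function() {
  tibble::tribble(
    ~primaryid, ~outc_cod,
    "11",       "HO",
    "31",       "OT"
  )
}

tiny_ther <- function() {
  tibble::tribble(
    ~primaryid, ~dsg_drug_seq, ~start_dt, ~end_dt,
    "11",       1L,            20220101L, 20220120L,
    "21",       1L,            202201L,   NA,
    "31",       1L,            20230301L, NA
  )
}

tiny_tables <- function() {
  structure(list(demo = tiny_demo(), drug = tiny_drug(), reac = tiny_reac(),
                 outc = tiny_outc(), ther = tiny_ther()),
            class = c("faers_tables", "list"))
}

tiny_dictionary <- function() {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tibble::tribble(
    ~pt,        ~soc,
    "Nausea",   "Gastrointestinal disorders",
    "Vomiting", "Gastrointestinal disorders",
    "Headache", "Nervous system disorders"
  ), path)
  read_pt_soc_dictionary(path)
}

# events table constructor for disproportionality tests
make_events <- function(...) {
  tibble::tribble(~caseid, ~pt, ~soc, ...)
}
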