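# Frequency tables, percentage convention, onset summaries, comparisons.

test_that("percentages follow round-half-up at 2 decimals", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(percent_half_up(6207, 19289), 32.18)
  expect_true(is.na(percent_half_up(1, 0)))
})

test_that("frequency tables recompute their percentages from their own counts", {
  tbl <- frequency_table(c("A", "B"), c(30, 70))
  expect_equal(tbl$percent, c(30, 70))
  expect_equal(attr(tbl, "denominator"), 100)
  recomputed <- percent_half_up(tbl$count, attr(tbl, "denominator"))
  expect_equal(tbl$percent, recomputed)
})

test_that("demographics tables bucket year, age band, sex and country", {
  cases <- tibble::tibble(
    caseid = as.character(1:6),
    fda_dt = c(20220101L, 20220601L, 20210301L, 20230101L, 20220815L, 20200102L),
    age_years = c(30, 40, 70, NA, 65, 35),
    sex = c("F", "F", "M", NA, "F", "M"),
    country = c("US", "US", "GB", "US", NA, "CA")
  )
  tbl <- demographics_table(cases)
  year <- tbl[tbl$section == "year", ]
  expect_equal(year$count[year$label == "2022"], 3)
  expect_equal(year$percent[year$label == "2022"], 50)
  age <- tbl[tbl$section == "age", ]
  expect_equal(age$count, c(1L, 3L, 1L, 1L)) # <35, 35-65 (inclusive), >65, unknown
  country <- tbl[tbl$section == "country", ]
  expect_equal(country$label[[1]], "US")
  expect_equal(country$count[[1]], 3)

  empty <- demographics_table(cases[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "denominator"), 0)
})

test_that("SOC and PT frequency tables count events with deterministic ties", {
  events <- make_events(
    "1", "Nausea", "GI",
    "1", "Vomiting", "GI",
    "2", "Rash", "Skin",
    "3", "Alopecia", "Skin"
  )
  soc <- soc_frequency_table(events)
  expect_equal(soc$label, c("GI", "Skin"))
  expect_equal(soc$percent, c(50, 50))
  expect_equal(sum(soc$count), nrow(events))

  pt <- pt_frequency_table(events, top_k = 3)
  expect_equal(nrow(pt), 3)
  # all counts tie at 1 -> alphabetical
  expect_equal(pt$label, c("Alopecia", "Nausea", "Rash"))
  full <- pt_frequency_table(events, top_k = Inf)
  expect_equal(sum(full$count), nrow(events))

  single <- soc_frequency_table(make_events("1", "Nausea", "GI"))
  expect_equal(single$percent, 100)
})

test_that("serious-outcome rate counts cases with any serious code", {
  cases <- tibble::tibble(
    caseid = as.character(1:4),
    outcomes = list("DE", c("OT", "HO"), "OT", character(0))
  )
  expect_equal(serious_outcome_rate(cases, "DE")$percent, 25)
  expect_equal(serious_outcome_rate(cases)$count, 2) # DE and HO cases
  expect_equal(serious_outcome_rate(cases, character(0))$percent, 0)
})

test_that("onset summaries use linear-interpolation quantiles", {
  x <- tibble::tibble(onset_days = c(1L, 1L, 4L, 32L, 60L))
  s <- onset_summary(x)
  expect_equal(c(s$q1, s$median, s$q3), c(1, 4, 32))
  expect_equal(s$n_usable, 5)

  none <- onset_summary(tibble::tibble(onset_days = NA_integer_))
  expect_false(none$defined)
  expect_equal(none$n_usable, 0)
})

test_that("simulated onsets recover the configured median", {
  sim <- simulate_reports(sim_config(n_cases_target = 5000,
                                     n_cases_background = 0,
                                     duplicate_fraction = 0, seed = 41))
  s <- onset_summary(tibble::tibble(onset_days = sim$truth$cases$onset_days))
  expect_gte(s$median, 3)
  expect_lte(s$median, 5)
})

test_that("source comparison joins on label and flags one-sided rows", {
  faers <- frequency_table(c("GI", "Nervous"), c(80, 20))
  social <- frequency_table(c("GI", "Psych"), c(60, 40))
  cmp <- compare_sources(faers, social)
  expect_equal(cmp$abs_diff[cmp$label == "GI"], 20)
  expect_equal(cmp$only_in[cmp$label == "Nervous"], "faers")
  expect_equal(cmp$only_in[cmp$label == "Psych"], "social")
  expect_true(is.na(cmp$only_in[cmp$label == "GI"]))
})

test_that("simulated serious-outcome rates track the configured probabilities", {
  cfg <- sim_config(n_cases_target = 5000, n_cases_background = 0,
                    duplicate_fraction = 0, seed = 43)
  sim <- simulate_reports(cfg)
  kept <- deduplicate_reports(sim$tables$demo)
  cases <- assemble_cases(sim$tables, kept)
  rate <- serious_outcome_rate(cases)$percent / 100
  p <- 1 - prod(1 - cfg$serious_outcome_prob[c("DE", "LT", "HO", "DS", "CA", "RI")])
  se <- sqrt(p * (1 - p) / nrow(cases))
  expect_lt(abs(rate - p), 3 * se)
})
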