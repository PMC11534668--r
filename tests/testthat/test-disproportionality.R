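# ROR engine, signal detection, Venn partition, route comparison.

test_that("compute_ror reproduces hand-computed tables", {
  # 2.25 * exp(+/- 1.96 * sqrt(1/20 + 1/80 + 1/10 + 1/90)), worked by hand
  res <- compute_ror(20, 80, 10, 90)
  expect_equal(res$ror, 2.25)
  expect_equal(res$ci_low, 0.994, tolerance = 1e-3)
  expect_equal(res$ci_high, 5.092, tolerance = 1e-3)
  expect_false(res$is_signal)

  res <- compute_ror(50, 950, 100, 8900)
  expect_equal(res$ror, 4.684, tolerance = 1e-3)
  expect_equal(res$ci_low, 3.31, tolerance = 1e-2)
  expect_equal(res$ci_high, 6.62, tolerance = 1e-2)
  expect_true(res$is_signal)
})

test_that("symmetric tables give ROR exactly 1 and never signal", {
  res <- compute_ror(15, 85, 15, 85)
  expect_identical(res$ror, 1)
  expect_false(res$is_signal)
})

test_that("zero cells and low counts are non-evaluable, not patched", {
  expect_false(compute_ror(0, 100, 10, 90)$evaluable)
  expect_false(compute_ror(10, 0, 10, 90)$evaluable)
  expect_false(compute_ror(2, 98, 10, 90, min_count = 3)$evaluable)
  expect_true(compute_ror(2, 98, 10, 90, min_count = 2)$evaluable)
  expect_error(compute_ror(-1, 10, 10, 10), class = "faersignal_table_error")

  # opt-in Haldane-Anscombe correction rescues zero cells
  res <- compute_ror(5, 95, 0, 100, correction = "haldane")
  expect_true(res$evaluable)
  expect_equal(res$ror, (5.5 / 0.5) / (95.5 / 100.5))
})

test_that("ROR is invariant to scaling the non-case margins and reciprocal under swap", {
  base <- compute_ror(12, 88, 7, 93)
  scaled <- compute_ror(12, 88 * 5, 7, 93 * 5)
  expect_equal(scaled$ror, base$ror)

  swapped <- compute_ror(7, 93, 12, 88)
  expect_equal(swapped$ror, 1 / base$ror)
  expect_equal(swapped$ci_low, 1 / base$ci_high)
  expect_equal(swapped$ci_high, 1 / base$ci_low)
})

test_that("the interval contains the estimate and tightens as cells scale up", {
  for (k in c(1, 2, 10)) {
    res <- compute_ror(8 * k, 92 * k, 5 * k, 95 * k)
    expect_lte(res$ci_low, res$ror)
    expect_gte(res$ci_high, res$ror)
  }
  w <- purrr::map_dbl(c(1, 2, 10),
                      ~ with(compute_ror(8 * .x, 92 * .x, 5 * .x, 95 * .x),
                             log(ci_high) - log(ci_low)))
  expect_true(all(diff(w) < 0))
})

test_that("contingency tables count cases once per term", {
  events <- make_events(
    "x", "Nausea", "Gastrointestinal disorders",
    "y", "Headache", "Nervous system disorders"
  )
  tbl <- build_contingency(events, "Nausea", "x", "y")
  expect_equal(unlist(tbl[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 0L, 0L, 1L))

  # same PT listed twice for one case still contributes 1 to a
  events2 <- dplyr::bind_rows(events, events[1, ])
  expect_equal(build_contingency(events2, "Nausea", "x", "y")$a, 1)

  expect_error(build_contingency(events, "Nausea", c("x", "y"), "y"),
               class = "faersignal_cohort_error")
})

test_that("detect_signals matches generator bookkeeping on a tiny simulation", {
  sim <- simulate_reports(sim_config(n_cases_target = 400,
                                     n_cases_background = 400,
                                     duplicate_fraction = 0, seed = 23))
  events <- dplyr::inner_join(sim$tables$reac,
                              dplyr::select(sim$tables$demo, primaryid, caseid),
                              by = "primaryid") |>
    dplyr::transmute(caseid, pt, soc = NA_character_)
  truth <- sim$truth$cases
  t_ids <- truth$caseid[truth$arm == "target"]
  b_ids <- truth$caseid[truth$arm == "background"]
  res <- detect_signals(events, t_ids, b_ids, min_count = 1)
  # ground-truth cell counts recomputed independently from the raw draw
  for (term in c("Nausea", "Back pain")) {
    with_term <- unique(events$caseid[events$pt == term])
    expect_equal(res$a[res$term == term], sum(t_ids %in% with_term))
    expect_equal(res$c[res$term == term], sum(b_ids %in% with_term))
  }
  expect_equal(attr(res, "n_terms_tested"), nrow(res))
  # sorted by descending ROR among evaluable, ties broken by term
  ev <- res[res$evaluable, ]
  expect_true(all(diff(ev$ror) <= 1e-12))
})

test_that("an empty target cohort yields an empty result", {
  events <- make_events("y", "Nausea", "GI")
  res <- detect_signals(events, character(0), "y")
  expect_equal(nrow(res), 0)
  expect_s3_class(res, "ror_signals")
})

test_that("venn partition follows set algebra", {
  left <- make_events("1", "A", "s", "1", "B", "s", "2", "C", "s")
  right <- make_events("3", "B", "s", "3", "C", "s", "4", "D", "s")
  part <- venn_partition(left, right)
  expect_equal(part$unique_left, "A")
  expect_equal(part$shared, c("B", "C"))
  expect_equal(part$unique_right, "D")

  same <- venn_partition(left, left)
  expect_length(same$unique_left, 0)
  expect_equal(same$shared, c("A", "B", "C"))

  disjoint <- venn_partition(left, make_events("5", "Z", "s"))
  expect_length(disjoint$shared, 0)
  expect_equal(tidy(part)$side[tidy(part)$term == "A"], "unique_left")
})

test_that("unique-PT signals are restricted to formulation-unique terms", {
  events <- make_events(
    "o1", "OnlyOral", "s",
    "o1", "Shared", "s",
    "s1", "OnlySub", "s",
    "s2", "Shared", "s",
    "b1", "OnlyOral", "s",
    "b2", "OnlySub", "s",
    "b3", "Shared", "s"
  )
  res <- unique_pt_signals(events, oral_ids = "o1",
                           subcutaneous_ids = c("s1", "s2"),
                           background_ids = c("b1", "b2", "b3", "b4"),
                           min_count = 1)
  expect_equal(res$oral$term, "OnlyOral")
  expect_equal(res$subcutaneous$term, "OnlySub")
  expect_false("Shared" %in% c(res$oral$term, res$subcutaneous$term))
})

test_that("route-versus-route reports the lower bound as ROR_025", {
  events <- make_events(
    "o1", "Nausea", "Gastrointestinal disorders",
    "o2", "Nausea", "Gastrointestinal disorders",
    "s1", "Nausea", "Gastrointestinal disorders",
    "s2", "Nausea", "Gastrointestinal disorders"
  )
  res <- route_vs_route_ror(events, "Gastrointestinal disorders",
                            oral_ids = c("o1", "o2", "o3", "o4"),
                            subcutaneous_ids = c("s1", "s2", "s3", "s4"),
                            level = "soc", min_count = 1)
  expect_equal(res$ror, 1)
  expect_equal(res$ror_025, res$ci_low)

  empty <- route_vs_route_ror(events, "Gastrointestinal disorders",
                              oral_ids = character(0),
                              subcutaneous_ids = c("s1", "s2"))
  expect_false(empty$evaluable)
})

test_that("tidy and glance expose broom-shaped accessors", {
  events <- make_events("x", "Nausea", "GI", "y", "Nausea", "GI",
                        "x", "Rash", "Skin")
  res <- detect_signals(events, c("x", "x2", "x3", "x4"),
                        c("y", "y2", "y3", "y4"), min_count = 1)
  td <- tidy(res)
  expect_named(td, c("term", "level", "estimate", "conf.low", "conf.high",
                     "n_reports", "evaluable", "is_signal"))
  gl <- glance(res)
  expect_equal(gl$n_target, 4)
  expect_equal(gl$n_terms_tested, 2)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
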