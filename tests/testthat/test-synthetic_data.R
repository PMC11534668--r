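# Generator contracts: reproducibility, embedded odds parameterization,
# duplicate bookkeeping, config validation.

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_cases_target = 200, n_cases_background = 200,
                    duplicate_fraction = 0.15, seed = 42)
  s1 <- simulate_reports(cfg)
  s2 <- simulate_reports(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)

  r1 <- simulate_coded_reviews(cfg, n_reviews = 50)
  r2 <- simulate_coded_reviews(cfg, n_reviews = 50)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_coded_reviews(r1, p1)
  write_coded_reviews(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_reports(sim_config(n_cases_target = 10,
                                        n_cases_background = 10, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("per-arm occurrence probabilities encode the embedded odds ratio exactly", {
  cat <- tibble::tibble(pt = c("A", "B", "C"), soc = "S", ror = c(0.5, 1, 36))
  cfg <- sim_config(pt_catalog = cat, p_background = 0.01, seed = 1)
  p_t <- cfg$pt_catalog$p_target
  p_b <- cfg$pt_catalog$p_background
  implied <- (p_t / (1 - p_t)) / (p_b / (1 - p_b))
  expect_equal(implied, c(0.5, 1, 36), tolerance = 1e-12)
})

test_that("infeasible embedded odds are a hard error naming the PT", {
  cat <- tibble::tibble(pt = c("OK", "Broken"), soc = "S", ror = c(1, Inf))
  expect_error(sim_config(pt_catalog = cat), "Broken",
               class = "faersignal_config_error")
  expect_error(sim_config(pt_catalog = tibble::tibble(pt = "N", soc = "S",
                                                      ror = -1)),
               class = "faersignal_config_error")
})

test_that("duplicate versions share a caseid with increasing primaryid and non-decreasing fda_dt", {
  cfg <- sim_config(n_cases_target = 500, n_cases_background = 500,
                    duplicate_fraction = 0.2, seed = 5)
  sim <- simulate_reports(cfg)
  demo <- sim$tables$demo
  expect_gt(nrow(demo), dplyr::n_distinct(demo$caseid))
  expect_equal(dplyr::n_distinct(demo$caseid), 1000)
  ordered <- demo |>
    dplyr::group_by(caseid) |>
    dplyr::arrange(as.numeric(primaryid), .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(fda_dt) >= 0) &&
                       !is.unsorted(as.numeric(primaryid)))
  expect_true(all(ordered$ok))
})

test_that("every case has at least one reaction and target cases a PS target drug", {
  sim <- simulate_reports(sim_config(n_cases_target = 150,
                                     n_cases_background = 150, seed = 8))
  reac_pids <- unique(sim$tables$reac$primaryid)
  expect_true(all(sim$tables$demo$primaryid %in% reac_pids))
  ps <- sim$tables$drug |>
    dplyr::filter(role_cod == "PS",
                  grepl("semaglutide|ozempic|wegovy|rybelsus",
                        tolower(drugname)))
  target_cases <- sim$truth$cases$caseid[sim$truth$cases$arm == "target"]
  expect_setequal(intersect(unique(substr(ps$primaryid, 1, 8)), target_cases),
                  target_cases)
})

test_that("the empirical ROR of a strong embedded signal lands near its target", {
  # closed-form: at n = 5000/arm and p_b = 0.01 the delta-method 95% interval
  # around ROR = 5 stays within [4, 6.25]
  cat <- tibble::tibble(pt = "Marker", soc = "S", ror = 5)
  cfg <- sim_config(n_cases_target = 5000, n_cases_background = 5000,
                    pt_catalog = cat, duplicate_fraction = 0, seed = 77)
  sim <- simulate_reports(cfg)
  events <- dplyr::inner_join(sim$tables$reac,
                              dplyr::select(sim$tables$demo, primaryid, caseid),
                              by = "primaryid") |>
    dplyr::transmute(caseid, pt, soc = "S")
  truth <- sim$truth$cases
  res <- detect_signals(events, truth$caseid[truth$arm == "target"],
                        truth$caseid[truth$arm == "background"])
  ror <- res$ror[res$term == "Marker"]
  expect_gt(ror, 4)
  expect_lt(ror, 6.25)
})

test_that("an all-female review config yields only female reviews", {
  cfg <- sim_config(female_prob = 1, seed = 2)
  reviews <- simulate_coded_reviews(cfg, n_reviews = 100)
  expect_true(all(reviews$sex == "F"))
  expect_true(all(lengths(reviews$pts) >= 1 & lengths(reviews$pts) <= 5))
})
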