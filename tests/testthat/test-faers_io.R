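# Quarterly-file dialect: parsing, validation, round-trips, auxiliary files.

test_that("well-formed DEMO lines parse one record each", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$reporter_country$occp_cod",
    "11$1$20220110$20220105$62$YR$F$US$MD",
    "21$2$20220215$$$$M$US$CN",
    "31$3$20230301$2023$45$YR$F$GB$"
  ), file.path(dir, "DEMO23Q1.txt"))
  demo <- suppressMessages(faersignal:::read_faers_table(
    file.path(dir, "DEMO23Q1.txt"), "demo"))
  expect_equal(nrow(demo), 3)
  expect_equal(demo$primaryid, c("11", "21", "31"))
  expect_equal(demo$age, c(62, NA, 45))
  expect_true(is.na(demo$occp_cod[[3]]))
  expect_equal(date_precision(demo$event_dt), c("day", NA, "year"))
})

test_that("lines with the wrong delimiter count are skipped and counted", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$pt",
    "11$Nausea",
    "21$Nausea$extra-field",
    "31"
  ), file.path(dir, "REAC23Q1.txt"))
  reac <- suppressMessages(faersignal:::read_faers_table(
    file.path(dir, "REAC23Q1.txt"), "reac"))
  expect_equal(nrow(reac), 1)
  expect_equal(attr(reac, "n_skipped"), 2)
})

test_that("records violating field-domain invariants are skipped, not kept", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$drug_seq$role_cod$drugname$route$dose_form$dose_freq",
    "11$1$PS$OZEMPIC$$$",
    "21$1$XX$OZEMPIC$$$",
    "31$0$PS$OZEMPIC$$$"
  ), file.path(dir, "DRUG23Q1.txt"))
  drug <- suppressMessages(faersignal:::read_faers_table(
    file.path(dir, "DRUG23Q1.txt"), "drug"))
  expect_equal(drug$primaryid, "11")
  expect_equal(attr(drug, "n_skipped"), 2)
})

test_that("missing table file and bad header are hard errors naming the file", {
  dir <- withr::local_tempdir()
  expect_error(suppressMessages(read_quarter(dir, "23Q1")),
               "DEMO23Q1", class = "faersignal_io_error")
  write_quarter(tiny_tables(), dir, "23Q1")
  writeLines(c("foo$bar", "1$2"), file.path(dir, "OUTC23Q1.txt"))
  expect_error(suppressMessages(read_quarter(dir, "23Q1")),
               "header", class = "faersignal_io_error")
})

test_that("write then read round-trips every field exactly", {
  dir <- withr::local_tempdir()
  write_quarter(tiny_tables(), dir, "23Q1")
  back <- suppressMessages(read_quarter(dir, "23Q1"))
  for (tb in names(tiny_tables())) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(tiny_tables()[[tb]]),
                 info = tb)
  }
})

test_that("a randomized simulated batch round-trips through the dialect", {
  sim <- simulate_reports(sim_config(n_cases_target = 60,
                                     n_cases_background = 60,
                                     duplicate_fraction = 0.2, seed = 11))
  dir <- withr::local_tempdir()
  write_quarter(sim$tables, dir, "SIM")
  back <- suppressMessages(read_quarter(dir, "SIM"))
  for (tb in names(sim$tables)) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(sim$tables[[tb]]),
                 info = tb)
  }
})

test_that("empty record sets produce header-only files that read back empty", {
  empty <- purrr::map(tiny_tables(), ~ .x[0, ])
  dir <- withr::local_tempdir()
  write_quarter(empty, dir, "SIM")
  expect_equal(readLines(file.path(dir, "DEMOSIM.txt")),
               paste(names(tiny_demo()), collapse = "$"))
  back <- suppressMessages(read_quarter(dir, "SIM"))
  expect_true(all(purrr::map_int(back, nrow) == 0))
})

test_that("values containing the delimiter are refused at write time", {
  tabs <- tiny_tables()
  tabs$drug$drugname[[1]] <- "OZEMPIC $100"
  dir <- withr::local_tempdir()
  expect_error(write_quarter(tabs, dir, "SIM"), class = "faersignal_io_error")
})

test_that("PT dictionary lookups are case-normalized and conflicts are loud", {
  dict <- tiny_dictionary()
  expect_equal(dict$soc[dict$pt_key == "nausea"],
               "Gastrointestinal disorders")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pt\tsoc", path)
  expect_equal(nrow(read_pt_soc_dictionary(path)), 0)
  writeLines(c("pt\tsoc", "Nausea\tA", "NAUSEA \tB"), path)
  expect_error(read_pt_soc_dictionary(path), "nausea",
               class = "faersignal_dictionary_error")
})

test_that("coded reviews parse semicolon-joined PT lists", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("review_id,date,age,sex,pts",
               "R1,2023-01-01,50,F,Nausea;Hiccups",
               "R2,2023-02-01,60,M,"), path)
  expect_warning(reviews <- read_coded_reviews(path), "empty PT list")
  expect_equal(reviews$pts[[1]], c("Nausea", "Hiccups"))
  expect_length(reviews$pts[[2]], 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,date,age,sex,pts", "R1,2023-01-01,50,F,Nausea"), bad)
  expect_error(read_coded_reviews(bad), "review_id",
               class = "faersignal_io_error")
})

test_that("coded reviews round-trip and simulated batches hit the requested size", {
  cfg <- sim_config(seed = 3)
  reviews <- simulate_coded_reviews(cfg, n_reviews = 422)
  expect_equal(nrow(reviews), 422)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coded_reviews(reviews, path)
  back <- read_coded_reviews(path)
  expect_equal(back$pts, reviews$pts)
})
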