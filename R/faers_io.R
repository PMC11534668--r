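# Reading and writing the FAERS quarterly ASCII dialect and auxiliary files.
#
# The quarterly extracts are dollar-sign-delimited text with a header row and
# no quoting. Only the analytically used columns are modelled (see the field
# lists below); the full 30+ column FAERS schema is out of scope.

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "ther")

faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "route",
           "dose_form", "dose_freq"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
AGE_CODES <- c("DEC", "YR", "MON", "WK", "DY", "HR")

faers_file_name <- function(table, quarter_tag) {
  paste0(toupper(table), quarter_tag, ".txt")
}

# Split $-delimited lines into a character matrix, skipping lines whose
# delimiter count differs from the header. Embedded "$" in free text is not
# supported (FAERS does not quote); such lines shift the field count and are
# skipped with a log entry. Trailing empty fields are legal and padded back
# (strsplit drops them).
parse_dollar_lines <- function(lines, n_fields, file) {
  n_delim <- stringr::str_count(lines, fixed("$"))
  bad <- n_delim != n_fields - 1L
  if (any(bad)) {
    inform(sprintf("%s: skipped %d malformed line(s) (wrong field count)",
                   basename(file), sum(bad)))
  }
  parts <- strsplit(lines[!bad], "$", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", n_fields - length(p))))
  mat <- if (length(parts) > 0) {
    matrix(unlist(parts), ncol = n_fields, byrow = TRUE)
  } else {
    matrix(character(0), nrow = 0, ncol = n_fields)
  }
  list(mat = mat, n_skipped = sum(bad))
}

blank_to_na <- function(x) {
  x <- str_trim(x)
  x[x == ""] <- NA_character_
  x
}

as_int_or_na <- function(x) {
  suppressWarnings(as.integer(x))
}

# Per-table record validation. Returns a logical keep vector; invalid
# records are skipped (and counted), never silently altered.
validate_records <- function(tbl, table) {
  ok <- rep(TRUE, nrow(tbl))
  if (table == "demo") {
    ok <- ok & !is.na(tbl$primaryid) & !is.na(tbl$caseid)
    ok <- ok & (is.na(tbl$fda_dt) | is_valid_day_date(tbl$fda_dt))
    ok <- ok & (is.na(tbl$age_cod) | tbl$age_cod %in% AGE_CODES)
    ok <- ok & (is.na(tbl$sex) | tbl$sex %in% c("M", "F"))
  } else if (table == "drug") {
    ok <- ok & !is.na(tbl$primaryid)
    ok <- ok & !is.na(tbl$role_cod) & tbl$role_cod %in% ROLE_CODES
    ok <- ok & !is.na(tbl$drug_seq) & tbl$drug_seq >= 1L
  } else if (table == "reac") {
    ok <- ok & !is.na(tbl$primaryid)
    ok <- ok & !is.na(tbl$pt) & str_squish(tbl$pt) != ""
  } else if (table == "outc") {
    ok <- ok & !is.na(tbl$primaryid)
    ok <- ok & !is.na(tbl$outc_cod) & tbl$outc_cod %in% OUTCOME_CODES
  } else if (table == "ther") {
    ok <- ok & !is.na(tbl$primaryid)
    both <- is_valid_day_date(tbl$start_dt) & is_valid_day_date(tbl$end_dt)
    ok <- ok & (!both | tbl$start_dt <= tbl$end_dt)
  }
  ok
}

type_table <- function(mat, table) {
  cols <- faers_schema[[table]]
  tbl <- as_tibble(setNames(
    lapply(seq_along(cols), function(i) blank_to_na(mat[, i])), cols))
  int_cols <- intersect(cols, c("fda_dt", "event_dt", "start_dt", "end_dt",
                                "drug_seq", "dsg_drug_seq"))
  for (col in int_cols) tbl[[col]] <- as_int_or_na(tbl[[col]])
  if ("age" %in% cols) tbl$age <- suppressWarnings(as.numeric(tbl$age))
  tbl
}

read_faers_table <- function(path, table) {
  cols <- faers_schema[[table]]
  lines <- read_lines(path)
  if (length(lines) == 0) {
    stopf("unparseable header in %s: file is empty", basename(path),
          class = "faersignal_io_error")
  }
  header <- str_to_lower(str_trim(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  if (!identical(header, cols)) {
    stopf("unparseable header in %s: expected '%s', got '%s'",
          basename(path), paste(cols, collapse = "$"),
          paste(header, collapse = "$"), class = "faersignal_io_error")
  }
  body <- lines[-1]
  body <- body[str_trim(body) != ""]
  parsed <- parse_dollar_lines(body, length(cols), path)
  tbl <- type_table(parsed$mat, table)
  ok <- validate_records(tbl, table)
  if (any(!ok)) {
    inform(sprintf("%s: skipped %d invalid record(s)", basename(path), sum(!ok)))
  }
  structure(tbl[ok, ], n_skipped = parsed$n_skipped + sum(!ok))
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the five analytically used tables (`DEMO`, `DRUG`, `REAC`, `OUTC`,
#' `THER`) of one quarterly extract. Files are expected to be named
#' `<TABLE><quarter_tag>.txt` (e.g. `DEMO23Q1.txt`), dollar-sign-delimited
#' with a header row and no quoting, as in the FDA quarterly distribution.
#' Lines whose field count does not match the header, and records violating
#' a field-domain invariant (e.g. an unknown `role_cod`), are skipped and
#' counted, never silently kept.
#'
#' @param directory directory containing the table files.
#' @param quarter_tag tag embedded in the file names, e.g. `"23Q1"`.
#' @return a named list of tibbles (`demo`, `drug`, `reac`, `outc`, `ther`)
#'   of class `faers_tables`. `attr(x, "skipped")` holds the per-table count
#'   of skipped lines, `attr(x, "n_records")` the kept record counts.
#' @seealso [write_quarter()] for the inverse operation.
#' @export
read_quarter <- function(directory, quarter_tag) {
  paths <- file.path(directory, faers_file_name(FAERS_TABLES, quarter_tag))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stopf("missing FAERS table file(s): %s",
          paste(basename(paths[missing]), collapse = ", "),
          class = "faersignal_io_error")
  }
  tables <- map(setNames(seq_along(FAERS_TABLES), FAERS_TABLES),
                function(i) read_faers_table(paths[[i]], FAERS_TABLES[[i]]))
  skipped <- map_int(tables, ~ attr(.x, "n_skipped"))
  tables <- map(tables, ~ { attr(.x, "n_skipped") <- NULL; .x })
  inform(sprintf("read quarter %s: %s", quarter_tag,
                 paste(sprintf("%s=%d", FAERS_TABLES,
                               map_int(tables, nrow)), collapse = " ")))
  structure(tables, class = c("faers_tables", "list"),
            skipped = skipped, n_records = map_int(tables, nrow),
            quarter_tag = quarter_tag)
}

#' Write FAERS-style ASCII tables
#'
#' Writes the five-table record set in the same dollar-sign-delimited
#' dialect that [read_quarter()] consumes; `read_quarter(write_quarter(x))`
#' reproduces every record field exactly. Values containing the `$`
#' delimiter cannot be represented (the dialect has no quoting) and raise an
#' error.
#'
#' @param tables named list of tibbles as returned by [read_quarter()] or
#'   [simulate_reports()].
#' @param directory output directory (created if absent).
#' @param quarter_tag tag embedded in the file names.
#' @return invisibly, the written file paths.
#' @export
write_quarter <- function(tables, directory, quarter_tag) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", directory,
                   class = "faersignal_io_error")
  }
  paths <- character(0)
  for (table in FAERS_TABLES) {
    tbl <- tables[[table]]
    cols <- faers_schema[[table]]
    stopifnot(all(cols %in% names(tbl)))
    cells <- map(cols, function(col) {
      x <- as.character(tbl[[col]])
      x[is.na(x)] <- ""
      x
    })
    if (any(map_lgl(cells, ~ any(str_detect(.x, fixed("$")))))) {
      stopf("field values containing '$' cannot be written in the FAERS dialect (table %s)",
            table, class = "faersignal_io_error")
    }
    lines <- c(paste(cols, collapse = "$"),
               if (nrow(tbl) > 0) do.call(paste, c(cells, sep = "$")))
    path <- file.path(directory, faers_file_name(table, quarter_tag))
    write_lines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a PT to SOC dictionary
#'
#' Reads a two-column TSV (`pt`, `soc`) mapping MedDRA Preferred Terms to
#' their System Organ Class. Keys are case-normalized (trimmed, internal
#' whitespace collapsed, case-folded) for matching while the original casing
#' is kept for display. Duplicate PT rows with conflicting SOCs are a hard
#' error; exact duplicate rows collapse silently.
#'
#' A small synthetic demonstration dictionary covering common
#' semaglutide-associated terms ships with the package
#' (`system.file("extdata", "pt_soc_mini.tsv", package = "faersignal")`);
#' a licensed MedDRA export in the same two-column layout is a drop-in
#' replacement.
#'
#' @param path TSV path with header `pt<TAB>soc`.
#' @return tibble with columns `pt` (display casing), `pt_key` (normalized
#'   match key) and `soc`, one row per PT.
#' @export
read_pt_soc_dictionary <- function(path) {
  tbl <- read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("pt", "soc") %in% str_to_lower(names(tbl)))) {
    stopf("dictionary must have columns 'pt' and 'soc'",
          class = "faersignal_io_error")
  }
  names(tbl) <- str_to_lower(names(tbl))
  tbl <- tbl |>
    mutate(pt_key = pt_normalize(pt)) |>
    distinct(pt_key, soc, .keep_all = TRUE)
  dup <- tbl |> count(pt_key) |> filter(n > 1)
  if (nrow(dup) > 0) {
    stopf("conflicting SOC assignments for PT(s): %s",
          paste(dup$pt_key, collapse = ", "),
          class = "faersignal_dictionary_error")
  }
  tbl |> select(pt, pt_key, soc)
}

#' Read a coded patient-review table
#'
#' Reads a CSV of social-media drug reviews already coded to MedDRA
#' Preferred Terms (one row per review; the `pts` cell is a
#' semicolon-joined PT list). Reviews with an empty PT list are kept but
#' flagged with a warning, since a review that names no reaction carries no
#' event information.
#'
#' @param path CSV path with header; columns `review_id`, `date`, `age`,
#'   `sex`, `pts`.
#' @return tibble with one row per review; `pts` is a list-column of
#'   character vectors.
#' @export
read_coded_reviews <- function(path) {
  tbl <- read_csv(path, col_types = "ccncc", progress = FALSE)
  if (!"review_id" %in% names(tbl)) {
    stopf("coded review table is missing the mandatory 'review_id' column",
          class = "faersignal_io_error")
  }
  pts <- map(tbl$pts, function(cell) {
    if (is.na(cell) || str_trim(cell) == "") return(character(0))
    out <- str_squish(strsplit(cell, ";", fixed = TRUE)[[1]])
    out[out != ""]
  })
  n_empty <- sum(lengths(pts) == 0)
  if (n_empty > 0) {
    warn(sprintf("%d review(s) have an empty PT list", n_empty))
  }
  tbl$pts <- pts
  tbl
}

#' Write a coded patient-review table
#'
#' Inverse of [read_coded_reviews()]: the `pts` list-column is serialized as
#' a semicolon-joined cell.
#'
#' @param reviews tibble as returned by [read_coded_reviews()] or
#'   [simulate_coded_reviews()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_coded_reviews <- function(reviews, path) {
  out <- reviews
  out$pts <- map_chr(reviews$pts, paste, collapse = ";")
  write_csv(out, path, progress = FALSE)
  invisible(path)
}
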