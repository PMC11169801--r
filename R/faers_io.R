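# Ingestion of FAERS-dialect quarterly ASCII tables and the pipeline's
# normalized one-row-per-report table.

#' Declare a FAERS ASCII dialect
#'
#' The FAERS quarterly ASCII release is `$`-delimited text with a single
#' header line and no quoting or escaping. The dialect object names the
#' delimiter and the expected column set of each sub-table so that readers can
#' validate headers and tests can substitute e.g. comma-delimited fixtures.
#'
#' @param delim Single-character field delimiter. Default `"$"`.
#' @param schemas Named list with elements `demo`, `drug`, `reac`, `ther`,
#'   each a character vector of upper-case column names in file order.
#' @return A `faers_dialect` list.
#' @export
faers_dialect <- function(delim = "$", schemas = faers_schemas()) {
  stopifnot(nchar(delim) == 1L,
            all(c("demo", "drug", "reac", "ther") %in% names(schemas)))
  structure(list(delim = delim, schemas = schemas), class = "faers_dialect")
}

#' Default column schemas for the four FAERS sub-tables
#'
#' A minimal working subset of the post-2012 FAERS ASCII columns: the fields
#' the pipeline consumes, in file order.
#'
#' @return Named list of character vectors.
#' @export
faers_schemas <- function() {
  list(
    demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT",
             "AGE", "AGE_COD", "SEX", "OCCP_COD"),
    drug = c("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
    reac = c("PRIMARYID", "CASEID", "PT"),
    ther = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT", "END_DT")
  )
}

# Split-based reader for the unquoted FAERS dialect. Malformed rows (wrong
# field count) are captured in a rejects table with a reason, never dropped
# silently; header mismatch against the declared schema is fatal.
read_faers_table <- function(path, schema, delim, table_name) {
  if (!file.exists(path)) {
    abort_faersmine(paste0("input file does not exist: ", path), "faers_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    abort_faersmine(paste0("empty file (no header line): ", path), "faers_header_mismatch")
  }
  split_delim <- function(x) strsplit(x, delim, fixed = TRUE)
  header <- toupper(trimws(split_delim(lines[1])[[1]]))
  if (!identical(header, toupper(schema))) {
    bad <- union(setdiff(header, toupper(schema)), setdiff(toupper(schema), header))
    abort_faersmine(
      paste0("header of ", path, " does not match the ", table_name,
             " schema; offending columns: ", paste(bad, collapse = ", ")),
      "faers_header_mismatch")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rejects <- tibble::tibble(table = character(), line = integer(),
                            reason = character(), raw = character())
  if (length(body) == 0L) {
    cols <- rep(list(character()), length(schema))
    names(cols) <- header
    return(list(rows = tibble::as_tibble(cols), rejects = rejects))
  }
  fields <- split_delim(body)
  nf <- lengths(fields)
  # a line ending in the delimiter drops its trailing empty field in strsplit
  trailing <- endsWith(body, delim)
  nf_eff <- nf + as.integer(trailing & nf == length(schema) - 1L)
  ok <- nf_eff == length(schema)
  if (any(!ok)) {
    rejects <- tibble::tibble(table = table_name,
                              line = which(!ok) + 1L,
                              reason = "field_count",
                              raw = body[!ok])
  }
  fields <- lapply(fields[ok], function(f) {
    trimws(c(f, character(length(schema) - length(f))))
  })
  mat <- do.call(rbind, fields)
  rows <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                            .name_repair = "minimal")
  names(rows) <- header
  list(rows = rows, rejects = rejects)
}

#' Read one FAERS-style quarter (DEMO, DRUG, REAC, THER)
#'
#' Reads the four sub-tables without filtering. Malformed rows are collected
#' in `rejects` with machine-readable reasons; DRUG/REAC/THER rows whose
#' PRIMARYID is absent from DEMO are kept but flagged in `orphans`.
#'
#' @param demo_path,drug_path,reac_path,ther_path File paths.
#' @param dialect A [faers_dialect()].
#' @return A `raw_quarter` list with tibbles `demo`, `drug`, `reac`, `ther`
#'   (all columns character, verbatim), a `rejects` tibble
#'   (table, line, reason, raw) and an `orphans` tibble (table, primaryid).
#' @export
read_quarter <- function(demo_path, drug_path, reac_path, ther_path,
                         dialect = faers_dialect()) {
  paths <- list(demo = demo_path, drug = drug_path,
                reac = reac_path, ther = ther_path)
  parts <- purrr::imap(paths, function(p, nm) {
    read_faers_table(p, dialect$schemas[[nm]], dialect$delim, nm)
  })
  rejects <- dplyr::bind_rows(purrr::map(parts, "rejects"))
  tabs <- purrr::map(parts, "rows")
  demo_ids <- tabs$demo$PRIMARYID
  orphans <- dplyr::bind_rows(purrr::imap(tabs[c("drug", "reac", "ther")],
    function(tb, nm) {
      miss <- setdiff(unique(tb$PRIMARYID), demo_ids)
      tibble::tibble(table = rep(nm, length(miss)), primaryid = miss)
    }))
  structure(c(tabs, list(rejects = rejects, orphans = orphans)),
            class = "raw_quarter")
}

#' @export
print.raw_quarter <- function(x, ...) {
  cat("<raw_quarter>\n")
  for (nm in c("demo", "drug", "reac", "ther")) {
    cat(sprintf("  %s: %d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  cat(sprintf("  rejects: %d, orphan ids: %d\n", nrow(x$rejects), nrow(x$orphans)))
  invisible(x)
}

#' Parse FAERS date strings into partial dates
#'
#' FAERS date fields hold `YYYYMMDD`, `YYYYMM`, `YYYY`, or nothing. The
#' parser is total: every input maps to a precision class, never an error.
#' Precision `day` requires an 8-digit string naming a real calendar date;
#' 6-digit strings with a valid month get `month`; 4-digit strings get
#' `year`; empty/NA input is `missing`; everything else is `invalid`.
#'
#' @param raw Character vector of raw date strings.
#' @return A tibble with columns `raw`, `precision` (one of day, month, year,
#'   missing, invalid) and `ordinal_day` (integer days since 1970-01-01;
#'   present iff precision is `day`).
#' @export
#' @examples
#' parse_date(c("20230131", "202301", "2023", "", "20230231"))
parse_date <- function(raw) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- nchar(x)
  digits <- grepl("^[0-9]+$", x)
  precision <- rep("invalid", length(x))
  precision[x == ""] <- "missing"
  d8 <- digits & n == 8L
  dt <- rep(as.Date(NA), length(x))
  if (any(d8)) {
    parsed <- as.Date(x[d8], format = "%Y%m%d")
    # as.Date rolls nothing: impossible dates come back NA
    dt[d8] <- parsed
    precision[d8] <- ifelse(is.na(parsed), "invalid", "day")
  }
  d6 <- digits & n == 6L
  if (any(d6)) {
    mo <- as.integer(substr(x[d6], 5, 6))
    precision[d6] <- ifelse(mo >= 1L & mo <= 12L, "month", "invalid")
  }
  precision[digits & n == 4L] <- "year"
  tibble::tibble(
    raw = x,
    precision = precision,
    ordinal_day = ifelse(precision == "day", as.integer(dt), NA_integer_)
  )
}

# ---- normalized report table -------------------------------------------

reports_atomic_cols <- c("caseid", "primaryid", "fda_dt", "sex", "age_years",
                         "occupation_code", "reporter_class", "report_year",
                         "event_date", "therapy_start")

#' Construct a normalized report table
#'
#' One row per report version: identifiers and receipt date, demographics,
#' reporter class, raw (possibly partial) event and therapy-start date
#' strings, and nested drug and reaction lists.
#'
#' @param caseid,primaryid,fda_dt Numeric identifier / receipt-date vectors
#'   (FDA_DT and PRIMARYID are orderable integers in the FAERS release).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param age_years Age in years or `NA`.
#' @param occupation_code Reporter occupation code (e.g. `"MD"`) or `NA`.
#' @param reporter_class `"medical"`, `"non_medical"` or `"unknown"`.
#' @param report_year Integer receipt year.
#' @param event_date,therapy_start Raw date strings (see [parse_date()]).
#' @param drugs List; each element a list with character vectors `name` and
#'   `role` (roles `PS`, `SS`, `C`, `I`).
#' @param reactions List of character vectors of MedDRA PT strings.
#' @return A tibble of class `faers_reports`.
#' @export
new_reports <- function(caseid = double(), primaryid = double(),
                        fda_dt = double(), sex = character(),
                        age_years = double(), occupation_code = character(),
                        reporter_class = character(), report_year = integer(),
                        event_date = character(), therapy_start = character(),
                        drugs = list(), reactions = list()) {
  out <- tibble::tibble(
    caseid = as.double(caseid), primaryid = as.double(primaryid),
    fda_dt = as.double(fda_dt), sex = as.character(sex),
    age_years = as.double(age_years),
    occupation_code = as.character(occupation_code),
    reporter_class = as.character(reporter_class),
    report_year = as.integer(report_year),
    event_date = as.character(event_date),
    therapy_start = as.character(therapy_start),
    drugs = drugs, reactions = reactions
  )
  class(out) <- c("faers_reports", class(out))
  out
}

as_faers_reports <- function(x) {
  if (!inherits(x, "faers_reports")) class(x) <- c("faers_reports", class(x))
  x
}

#' Build normalized reports from a raw quarter
#'
#' Joins DEMO, DRUG, REAC and THER into the one-row-per-report table the
#' rest of the pipeline consumes. The event date comes from DEMO's EVENT_DT
#' (default) or THER's END_DT; the therapy start date is the START_DT of the
#' report's lowest drug-sequence THER row (the primary-suspect drug occupies
#' sequence 1 in FAERS).
#'
#' @param quarter A `raw_quarter` from [read_quarter()].
#' @param event_date_source `"demo"` (EVENT_DT) or `"ther_end"` (END_DT).
#' @return A `faers_reports` tibble.
#' @export
build_reports <- function(quarter, event_date_source = c("demo", "ther_end")) {
  stopifnot(inherits(quarter, "raw_quarter"))
  event_date_source <- match.arg(event_date_source)
  demo <- quarter$demo
  num <- function(x) suppressWarnings(as.double(x))
  ids <- demo$PRIMARYID

  drug_by_id <- split(quarter$drug[c("DRUGNAME", "ROLE_COD")],
                      factor(quarter$drug$PRIMARYID, levels = ids))
  reac_by_id <- split(trimws(quarter$reac$PT),
                      factor(quarter$reac$PRIMARYID, levels = ids))
  ther <- quarter$ther
  ther_first <- ther |>
    dplyr::mutate(.seq = num(.data$DSG_DRUG_SEQ)) |>
    dplyr::arrange(.data$PRIMARYID, .data$.seq) |>
    dplyr::distinct(.data$PRIMARYID, .keep_all = TRUE)
  ther_start <- setNames(ther_first$START_DT, ther_first$PRIMARYID)
  ther_end <- setNames(ther_first$END_DT, ther_first$PRIMARYID)

  fda_dt <- num(demo$FDA_DT)
  event_raw <- if (event_date_source == "demo") {
    demo$EVENT_DT
  } else {
    unname(ther_end[ids])
  }
  event_raw[is.na(event_raw)] <- ""
  start_raw <- unname(ther_start[ids])
  start_raw[is.na(start_raw)] <- ""
  occp <- trimws(demo$OCCP_COD)
  occp[occp == ""] <- NA_character_
  sex <- dplyr::case_match(toupper(trimws(demo$SEX)),
                           "M" ~ "male", "F" ~ "female",
                           .default = NA_character_)
  new_reports(
    caseid = num(demo$CASEID), primaryid = num(ids), fda_dt = fda_dt,
    sex = sex,
    age_years = age_to_years(num(demo$AGE), demo$AGE_COD),
    occupation_code = occp,
    reporter_class = classify_reporter(occp),
    report_year = as.integer(fda_dt %/% 10000),
    event_date = trimws(event_raw), therapy_start = trimws(start_raw),
    drugs = unname(lapply(drug_by_id, function(d) {
      list(name = as.character(trimws(d$DRUGNAME)),
           role = as.character(toupper(trimws(d$ROLE_COD))))
    })),
    reactions = unname(lapply(reac_by_id, as.character))
  )
}

#' Write / read the normalized report table
#'
#' The normalized table is tab-separated with the nested drug and reaction
#' lists serialized as JSON cells, so that
#' `read_normalized(write_normalized(x))` is the identity.
#'
#' @param reports A `faers_reports` tibble.
#' @param path Output (input) file path.
#' @return `write_normalized()` returns `path` invisibly; `read_normalized()`
#'   returns the `faers_reports` tibble.
#' @export
write_normalized <- function(reports, path) {
  flat <- tibble::as_tibble(reports[reports_atomic_cols])
  flat$drugs <- vapply(reports$drugs, function(d) {
    as.character(jsonlite::toJSON(list(name = as.character(d$name),
                                       role = as.character(d$role))))
  }, character(1))
  flat$reactions <- vapply(reports$reactions, function(r) {
    as.character(jsonlite::toJSON(as.character(r)))
  }, character(1))
  # JSON cells contain double quotes but never literal tabs/newlines
  # (jsonlite escapes control characters), so quoting is disabled outright
  readr::write_tsv(flat, path, na = "NA", quote = "none", escape = "none")
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  flat <- readr::read_tsv(path, na = "NA", quote = "", col_types = readr::cols(
    caseid = "d", primaryid = "d", fda_dt = "d", sex = "c", age_years = "d",
    occupation_code = "c", reporter_class = "c", report_year = "i",
    event_date = "c", therapy_start = "c", drugs = "c", reactions = "c"
  ))
  new_reports(
    caseid = flat$caseid, primaryid = flat$primaryid, fda_dt = flat$fda_dt,
    sex = flat$sex, age_years = flat$age_years,
    occupation_code = flat$occupation_code,
    reporter_class = flat$reporter_class, report_year = flat$report_year,
    event_date = flat$event_date, therapy_start = flat$therapy_start,
    drugs = lapply(flat$drugs, function(js) {
      d <- jsonlite::fromJSON(js)
      list(name = as.character(unlist(d$name)), role = as.character(unlist(d$role)))
    }),
    reactions = lapply(flat$reactions, function(js) {
      as.character(unlist(jsonlite::fromJSON(js)))
    })
  )
}

#' Write the rejects report of a raw quarter
#'
#' @param quarter A `raw_quarter`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_rejects <- function(quarter, path) {
  readr::write_tsv(quarter$rejects, path, na = "NA")
  invisible(path)
}
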