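# Deduplication, drug-synonym matching, primary-suspect cohort selection,
# reporter classification, age conversion and PT -> SOC mapping.

#' Deduplicate case reports by CASEID / FDA_DT / PRIMARYID
#'
#' FAERS carries several versions of the same case. For each CASEID the most
#' recent version is kept: latest FDA_DT, and among receipt-date ties the
#' largest PRIMARYID. Output is sorted by caseid, so the result is
#' deterministic and independent of input order; the operation is idempotent.
#' A tie on both FDA_DT and PRIMARYID cannot occur in real data; if injected,
#' the first-seen row is kept and a warning is emitted.
#'
#' @param reports A `faers_reports` tibble (see [new_reports()]).
#' @return The deduplicated `faers_reports` tibble, one row per caseid.
#' @export
deduplicate <- function(reports) {
  if (nrow(reports) == 0L) return(reports)
  ord <- order(reports$caseid, -reports$fda_dt, -reports$primaryid)
  sorted <- reports[ord, ]
  keep <- !duplicated(sorted$caseid)
  dup_key <- paste(sorted$caseid, sorted$fda_dt, sorted$primaryid)
  if (anyDuplicated(dup_key)) {
    warning("ties on (caseid, fda_dt, primaryid); keeping first seen",
            call. = FALSE)
    # order() is stable, so first seen in input order wins within exact ties
    sorted <- reports[order(reports$caseid, -reports$fda_dt, -reports$primaryid), ]
    keep <- !duplicated(sorted$caseid)
  }
  as_faers_reports(sorted[keep, ])
}

#' Define a target-drug query
#'
#' A drug is retrieved by its generic and brand names because FAERS reporters
#' use either. The canonical name is always part of the synonym set.
#'
#' @param canonical_name Generic name, e.g. `"patisiran"`.
#' @param synonyms Character vector of additional names
#'   (brand names, salt forms, development codes).
#' @return A `drug_query` list with normalized `canonical_name`, `synonyms`.
#' @export
#' @examples
#' drug_query("patisiran", c("ALN-TTR02", "onpattro", "patisiran sodium"))
drug_query <- function(canonical_name, synonyms = character()) {
  canonical <- normalize_term(canonical_name)
  structure(list(canonical_name = canonical,
                 synonyms = union(canonical, normalize_term(synonyms))),
            class = "drug_query")
}

#' Match a verbatim drug name against a drug query
#'
#' Verbatim FAERS names carry dose and formulation suffixes, so matching is
#' word-boundary containment of any synonym in the normalized name, not exact
#' equality: `"PATISIRAN SODIUM."` matches the patisiran query.
#'
#' @param drug_name Character vector of verbatim drug names.
#' @param query A [drug_query()].
#' @return Logical vector.
#' @export
match_drug <- function(drug_name, query) {
  stopifnot(inherits(query, "drug_query"))
  x <- normalize_term(drug_name)
  pats <- paste0("\\b", vapply(query$synonyms, escape_regex, character(1)), "\\b")
  Reduce(`|`, lapply(pats, function(p) grepl(p, x, perl = TRUE)),
         rep(FALSE, length(x)))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Select the primary-suspect cohort for a drug
#'
#' Keeps the reports in which the queried drug appears with role code `PS`
#' (primary suspect). With deduplicated input the cohort size equals the
#' number of unique caseids.
#'
#' @param reports Deduplicated `faers_reports`.
#' @param query A [drug_query()].
#' @return The cohort subset of `reports`.
#' @export
select_ps_cohort <- function(reports, query) {
  hit <- vapply(reports$drugs, function(d) {
    any(d$role == "PS" & match_drug(d$name, query))
  }, logical(1))
  as_faers_reports(reports[hit, ])
}

#' Classify reporter occupation codes
#'
#' FAERS occupation codes are mapped to a medical / non-medical dichotomy for
#' the reporter-type subgroup analysis: physicians, pharmacists, other health
#' professionals and health professionals (`MD`, `PH`, `OT`, `HP`) are
#' medical; consumers and lawyers (`CN`, `LW`) are non-medical; anything else
#' (including a missing code) is unknown.
#'
#' @param occupation_code Character vector (NA allowed).
#' @param medical_codes,non_medical_codes Configurable code sets.
#' @return Character vector: `"medical"`, `"non_medical"` or `"unknown"`.
#' @export
classify_reporter <- function(occupation_code,
                              medical_codes = c("MD", "PH", "OT", "HP"),
                              non_medical_codes = c("CN", "LW")) {
  code <- toupper(trimws(as.character(occupation_code)))
  out <- rep("unknown", length(code))
  out[!is.na(code) & code %in% medical_codes] <- "medical"
  out[!is.na(code) & code %in% non_medical_codes] <- "non_medical"
  out
}

#' Convert FAERS age values to years
#'
#' Applies the AGE_COD unit: decades (`DEC`), years (`YR`), months (`MON`),
#' weeks (`WK`), days (`DY`) and hours (`HR`). Results outside \[0, 150\]
#' years, unknown unit codes and missing inputs give `NA`; implausible values
#' are additionally reported via a warning rather than an error, because a
#' single bad demographic row must not stop a quarter.
#'
#' @param age_value Numeric vector.
#' @param age_unit_code Character vector of unit codes.
#' @return Numeric vector of ages in years (NA where unavailable).
#' @export
#' @examples
#' age_to_years(c(65, 6, 24), c("YR", "DEC", "MON"))
age_to_years <- function(age_value, age_unit_code) {
  factor_per_year <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                       DY = 1 / 365.25, HR = 1 / 8766)
  unit <- toupper(trimws(as.character(age_unit_code)))
  mult <- unname(factor_per_year[unit])
  out <- suppressWarnings(as.double(age_value)) * mult
  bad <- !is.na(out) & (out < 0 | out > 150)
  if (any(bad)) {
    warning(sprintf("%d age value(s) outside [0, 150] years set to NA",
                    sum(bad)), call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Load a PT -> SOC mapping table
#'
#' MedDRA itself is licensed and is not shipped; the pipeline consumes a
#' user-supplied two-column delimited table mapping each Preferred Term to
#' its primary System Organ Class. Lookup is case-insensitive after
#' normalization; a PT mapped to more than one SOC is an error.
#'
#' @param path Delimited text file with columns `pt`, `soc` (tab or comma).
#' @return A `meddra_map` object.
#' @export
read_meddra_map <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = "cc",
                           progress = FALSE)
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("pt", "soc") %in% names(tab)))
  meddra_map(tab$pt, tab$soc)
}

#' @rdname read_meddra_map
#' @param pt,soc Character vectors of equal length.
#' @export
meddra_map <- function(pt, soc) {
  key <- normalize_term(pt)
  dup <- unique(key[duplicated(key)])
  conflict <- dup[vapply(dup, function(k) {
    length(unique(soc[key == k])) > 1L
  }, logical(1))]
  if (length(conflict) > 0L) {
    abort_faersmine(paste0("PT mapped to multiple SOCs: ",
                           paste(conflict, collapse = ", ")),
                    "meddra_map_conflict")
  }
  keep <- !duplicated(key)
  structure(list(pt_to_soc = setNames(as.character(soc)[keep], key[keep])),
            class = "meddra_map")
}

#' Map Preferred Terms to System Organ Classes
#'
#' @param pt Character vector of PT strings (any case).
#' @param map A [meddra_map()].
#' @return Character vector of SOC names; PTs absent from the map are routed
#'   to the sentinel `"UNMAPPED"`.
#' @export
map_pt_to_soc <- function(pt, map) {
  stopifnot(inherits(map, "meddra_map"))
  soc <- unname(map$pt_to_soc[normalize_term(pt)])
  soc[is.na(soc)] <- "UNMAPPED"
  soc
}
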