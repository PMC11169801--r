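# Synthetic FAERS-like quarters with a ground-truth manifest, so that every
# pipeline stage (ingestion, dedup, cohort selection, ROR recovery, Weibull
# onset profiles, subgroup splits) is testable without any download.

#' Specification of one synthetic target drug
#'
#' @param name Canonical drug name.
#' @param synonyms Additional verbatim names the generator sprinkles over the
#'   DRUG rows (brand names, salt forms).
#' @param n_ps_reports Number of primary-suspect reports to plant.
#' @param signal_pts Tibble (or data.frame) with columns `pt`, `target_ror`
#'   and optionally `stratum` (`"all"`, `"medical"` or `"non_medical"`): each
#'   PT is reported with the probability that makes the expected report-level
#'   2x2 odds ratio against the background equal `target_ror`, within the
#'   named reporter stratum only when `stratum` is not `"all"`.
#' @param label_pts PTs on the drug's (synthetic) label.
#' @param weibull_shape,weibull_scale Time-to-onset distribution (days).
#' @return A `drug_spec` list.
#' @export
drug_spec <- function(name, synonyms = character(), n_ps_reports,
                      signal_pts, label_pts = character(),
                      weibull_shape = 1, weibull_scale = 180) {
  signal_pts <- tibble::as_tibble(signal_pts)
  stopifnot(all(c("pt", "target_ror") %in% names(signal_pts)),
            all(signal_pts$target_ror > 0),
            n_ps_reports >= 1, weibull_shape > 0, weibull_scale > 0)
  if (!"stratum" %in% names(signal_pts)) signal_pts$stratum <- "all"
  stopifnot(all(signal_pts$stratum %in% c("all", "medical", "non_medical")))
  structure(list(name = name, synonyms = synonyms,
                 n_ps_reports = as.integer(n_ps_reports),
                 signal_pts = signal_pts, label_pts = label_pts,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale),
            class = "drug_spec")
}

#' Simulation configuration for a synthetic quarter
#'
#' Defaults emulate a desk-scale version of a spontaneous-report window for
#' three transthyretin-inhibitor-like drugs: cohort sizes in the proportions
#' of the real reporting volumes scaled down tenfold against a 5000-report
#' background, a 15% duplicate-version rate, demographic missingness at the
#' rates typical of such reports (72% sex, 89% age missing), a
#' medical/non-medical reporter mix of roughly 59/40, and Weibull onset-time
#' profiles with shapes 0.81 / 1.48 / 0.81.
#'
#' @param n_background_reports Background (non-cohort) report count.
#' @param drug_specs List of [drug_spec()] objects.
#' @param duplicate_rate Fraction of cases that receive a second, newer
#'   report version (removed again by [deduplicate()]).
#' @param tie_fraction Fraction of injected duplicates sharing the original's
#'   FDA_DT, exercising the PRIMARYID tie-break.
#' @param missingness Named list of probabilities for `sex`, `age`,
#'   `occupation`.
#' @param date_precision_mix Named probabilities over `day`, `month`, `year`,
#'   `missing`, `invalid`, applied independently to event and therapy-start
#'   dates.
#' @param reporter_mix Named probabilities over `medical`, `non_medical`,
#'   `unknown`.
#' @param year_range Integer vector of receipt years to draw from.
#' @param malformed_row_rate Fraction of written DRUG lines corrupted (field
#'   dropped) to exercise reject capture; 0 disables injection.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param vocabulary PT vocabulary tibble (`pt`, `soc`, `base_prob`); default
#'   [pt_vocabulary()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_reports = 5000,
                       drug_specs = default_drug_specs(),
                       duplicate_rate = 0.15,
                       tie_fraction = 0.2,
                       missingness = list(sex = 0.716, age = 0.886,
                                          occupation = 0),
                       date_precision_mix = c(day = 0.5, month = 0.2,
                                              year = 0.1, missing = 0.15,
                                              invalid = 0.05),
                       reporter_mix = c(medical = 0.591, non_medical = 0.401,
                                        unknown = 0.008),
                       year_range = 2018:2023,
                       malformed_row_rate = 0,
                       seed = 1L,
                       vocabulary = pt_vocabulary()) {
  stopifnot(n_background_reports >= 1,
            all(vapply(drug_specs, inherits, logical(1), "drug_spec")),
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(unlist(missingness) >= 0), all(unlist(missingness) <= 1),
            abs(sum(date_precision_mix) - 1) < 1e-8,
            abs(sum(reporter_mix) - 1) < 1e-8)
  structure(list(n_background_reports = as.integer(n_background_reports),
                 drug_specs = drug_specs, duplicate_rate = duplicate_rate,
                 tie_fraction = tie_fraction, missingness = missingness,
                 date_precision_mix = date_precision_mix,
                 reporter_mix = reporter_mix, year_range = year_range,
                 malformed_row_rate = malformed_row_rate,
                 seed = as.integer(seed), vocabulary = vocabulary),
            class = "sim_config")
}

#' Default synthetic drug specifications
#'
#' Three drugs mirroring the structure (not the content) of a
#' transthyretin-inhibitor study window: an infusion drug with a large
#' cohort and an early-failure onset profile, a newer subcutaneous drug with
#' a small cohort and a wear-out profile, and an antisense drug in between.
#'
#' @return List of three [drug_spec()] objects.
#' @export
default_drug_specs <- function() {
  list(
    drug_spec("sirnafirst",
              synonyms = c("sirnafirst sodium", "firstpattro", "ALN-SYN01"),
              n_ps_reports = 216,
              signal_pts = tibble::tibble(
                pt = c("fatigue", "asthenia", "fall"),
                target_ror = c(8, 5, 3)),
              label_pts = c("vitamin a decreased", "muscle spasms",
                            "arthralgia", "dyspnoea", "fall"),
              weibull_shape = 0.81, weibull_scale = 325.5),
    drug_spec("sirnasecond",
              synonyms = c("secondvuttra", "sirnasecond sodium"),
              n_ps_reports = 26,
              signal_pts = tibble::tibble(
                pt = c("fall", "pain in extremity", "malaise"),
                target_ror = c(8, 6, 4)),
              label_pts = c("vitamin a decreased", "arthralgia", "dyspnoea"),
              weibull_shape = 1.48, weibull_scale = 131.9),
    drug_spec("asothird",
              synonyms = c("asothird sodium", "thirdsedi"),
              n_ps_reports = 104,
              signal_pts = tibble::tibble(
                pt = c("platelet count decreased", "blood creatinine increased",
                       "fatigue"),
                target_ror = c(10, 7, 4)),
              label_pts = c("platelet count decreased", "glomerulonephritis",
                            "vitamin a decreased", "arthralgia", "dyspnoea"),
              weibull_shape = 0.81, weibull_scale = 380.5)
  )
}

#' Bundled synthetic PT vocabulary
#'
#' About two hundred adverse-event Preferred Terms with an invented primary
#' SOC assignment and Zipf-like base reporting probabilities. The mapping is
#' synthetic (MedDRA is licensed and not shipped); it exists so tests and
#' simulations can exercise PT- and SOC-level logic.
#'
#' @return Tibble with columns `pt`, `soc`, `base_prob`.
#' @export
pt_vocabulary <- function() {
  path <- system.file("extdata", "pt_vocabulary.tsv", package = "faersmine",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccd", progress = FALSE)
}

#' Synthetic PT to SOC map from the bundled vocabulary
#'
#' @return A [meddra_map()] covering [pt_vocabulary()].
#' @export
synthetic_meddra_map <- function() {
  voc <- pt_vocabulary()
  meddra_map(voc$pt, voc$soc)
}

#' Tune the cohort reporting probability for a target ROR
#'
#' Given the background probability `q` that a report carries the PT, returns
#' the cohort probability `p` whose odds are `target_ror` times the
#' background odds: p = ror q / (1 - q + ror q). Report-level presence drawn
#' with these probabilities makes the expected 2x2 odds ratio equal the
#' target.
#'
#' @param base_pt_prob Background per-report probability, in (0, 1).
#' @param target_ror Target reporting odds ratio, > 0.
#' @return Cohort per-report probability in (0, 1).
#' @export
#' @examples
#' tune_signal_probability(0.01, 8)
tune_signal_probability <- function(base_pt_prob, target_ror) {
  stopifnot(all(base_pt_prob > 0), all(base_pt_prob < 1), all(target_ror > 0))
  odds <- target_ror * base_pt_prob / (1 - base_pt_prob)
  odds / (1 + odds)
}

# random YYYYMMDD receipt dates (day <= 28 so date arithmetic never overflows)
random_yyyymmdd <- function(n, years) {
  y <- sample(years, n, replace = TRUE)
  m <- sample(1:12, n, replace = TRUE)
  d <- sample(1:28, n, replace = TRUE)
  y * 10000 + m * 100 + d
}

yyyymmdd_plus_days <- function(ymd, days) {
  as.double(format(as.Date(sprintf("%08.0f", ymd), "%Y%m%d") + days, "%Y%m%d"))
}

# degrade a day-precision YYYYMMDD string per the precision mix
degrade_dates <- function(raw, mix) {
  prec <- sample(names(mix), length(raw), replace = TRUE, prob = mix)
  out <- raw
  out[prec == "month"] <- substr(raw[prec == "month"], 1, 6)
  out[prec == "year"] <- substr(raw[prec == "year"], 1, 4)
  out[prec == "missing"] <- ""
  inv <- prec == "invalid"
  out[inv] <- paste0(substr(raw[inv], 1, 6), "99")   # impossible day-of-month
  out
}

background_drug_pool <- function() {
  c("AMLODIPINE", "METFORMIN", "LISINOPRIL", "ATORVASTATIN", "OMEPRAZOLE",
    "LEVOTHYROXINE", "ALBUTEROL", "GABAPENTIN", "SERTRALINE", "FUROSEMIDE",
    "WARFARIN", "PREDNISONE", "INSULIN GLARGINE", "CLOPIDOGREL", "RAMIPRIL")
}

#' Generate a synthetic normalized report table with ground truth
#'
#' The in-memory twin of [generate_quarter()]: draws background and
#' per-drug primary-suspect reports, plants the configured PT signals at the
#' probabilities from [tune_signal_probability()], draws onset intervals from
#' each drug's Weibull distribution, degrades dates, applies demographic
#' missingness, and injects duplicate report versions that the Table-style
#' dedup rule must resolve.
#'
#' @param config A [sim_config()].
#' @return List with `reports` (a `faers_reports` tibble, duplicates
#'   included) and `truth` (a `synthetic_truth` list: per-drug caseids,
#'   planted signal probabilities and RORs, Weibull parameters, label PTs,
#'   injected duplicates, reporter classes).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  voc <- config$vocabulary
  voc$pt_norm <- normalize_term(voc$pt)

  n_bg <- config$n_background_reports
  n_drug <- vapply(config$drug_specs, function(d) d$n_ps_reports, integer(1))
  n_total <- n_bg + sum(n_drug)
  drug_of <- rep(c(0L, seq_along(config$drug_specs)), c(n_bg, n_drug))

  caseid <- 3000000 + seq_len(n_total)
  primaryid <- caseid * 100 + 1
  fda_dt <- random_yyyymmdd(n_total, config$year_range)

  # reporter class, then occupation codes consistent with it
  cls <- sample(names(config$reporter_mix), n_total, replace = TRUE,
                prob = config$reporter_mix)
  occ <- rep(NA_character_, n_total)
  occ[cls == "medical"] <- sample(c("MD", "PH", "OT", "HP"),
                                  sum(cls == "medical"), replace = TRUE)
  occ[cls == "non_medical"] <- sample(c("CN", "LW"),
                                      sum(cls == "non_medical"), replace = TRUE)
  occ[runif(n_total) < config$missingness$occupation] <- NA_character_
  cls <- classify_reporter(occ)

  sex <- sample(c("male", "female"), n_total, replace = TRUE)
  sex[runif(n_total) < config$missingness$sex] <- NA_character_
  age <- round(pmin(pmax(stats::rnorm(n_total, 67, 12), 18), 100))
  age[runif(n_total) < config$missingness$age] <- NA_real_

  # signal PTs are excluded from the filler pool so that report-level
  # presence of each signal PT is exactly Bernoulli(q) / Bernoulli(p)
  signal_pts_all <- unique(unlist(lapply(config$drug_specs,
                                         function(d) normalize_term(d$signal_pts$pt))))
  missing_voc <- setdiff(signal_pts_all, voc$pt_norm)
  if (length(missing_voc) > 0L) {
    abort_faersmine(paste0("signal PTs absent from the vocabulary: ",
                           paste(missing_voc, collapse = ", ")),
                    "unknown_signal_pt")
  }
  filler <- voc[!voc$pt_norm %in% signal_pts_all, ]
  n_fill <- 1L + stats::rpois(n_total, 1.2)
  fill_draws <- sample(filler$pt, sum(n_fill), replace = TRUE,
                       prob = filler$base_prob)
  reactions <- split(fill_draws, rep(seq_len(n_total), n_fill))
  names(reactions) <- NULL
  reactions <- lapply(reactions, as.character)

  # plant signal PTs: background reports at q, cohort reports at p (per
  # stratum when the spec says so)
  truth_signals <- list()
  for (pt in signal_pts_all) {
    q <- voc$base_prob[match(pt, voc$pt_norm)]
    prob <- rep(q, n_total)
    for (j in seq_along(config$drug_specs)) {
      sp <- config$drug_specs[[j]]$signal_pts
      sp$pt_norm <- normalize_term(sp$pt)
      row <- which(sp$pt_norm == pt)
      if (length(row) == 1L) {
        in_cohort <- drug_of == j
        if (sp$stratum[row] != "all") in_cohort <- in_cohort & cls == sp$stratum[row]
        prob[in_cohort] <- tune_signal_probability(q, sp$target_ror[row])
      }
    }
    hit <- runif(n_total) < prob
    reactions[hit] <- lapply(reactions[hit], function(r) c(r, pt))
    truth_signals[[pt]] <- list(pt = pt, base_prob = q)
  }

  # drugs: cohort reports carry the target drug as primary suspect (verbatim
  # name drawn from its synonym set); everyone can carry concomitants
  pool <- background_drug_pool()
  drugs <- vector("list", n_total)
  conc <- runif(n_total) < 0.3
  conc_name <- sample(pool, n_total, replace = TRUE)
  for (j in seq_along(config$drug_specs)) {
    spec <- config$drug_specs[[j]]
    idx <- which(drug_of == j)
    verbatim <- toupper(sample(c(spec$name, spec$synonyms), length(idx),
                               replace = TRUE))
    drugs[idx] <- Map(function(nm, cc, cn) {
      if (cc) list(name = c(nm, cn), role = c("PS", "C"))
      else list(name = nm, role = "PS")
    }, verbatim, conc[idx], conc_name[idx])
  }
  idx_bg <- which(drug_of == 0L)
  bg_name <- sample(pool, length(idx_bg), replace = TRUE)
  drugs[idx_bg] <- Map(function(nm, cc, cn) {
    if (cc) list(name = c(nm, cn), role = c("PS", "C"))
    else list(name = nm, role = "PS")
  }, bg_name, conc[idx_bg], conc_name[idx_bg])

  # therapy start and event dates; cohort onsets are Weibull draws
  start_dt <- random_yyyymmdd(n_total, config$year_range)
  onset <- round(runif(n_total, 0, 365))
  for (j in seq_along(config$drug_specs)) {
    spec <- config$drug_specs[[j]]
    idx <- which(drug_of == j)
    onset[idx] <- round(rweibull(length(idx), spec$weibull_shape,
                                 spec$weibull_scale))
  }
  event_raw <- sprintf("%08.0f", yyyymmdd_plus_days(start_dt, onset))
  start_raw <- sprintf("%08.0f", start_dt)
  event_date <- degrade_dates(event_raw, config$date_precision_mix)
  therapy_start <- degrade_dates(start_raw, config$date_precision_mix)

  reports <- new_reports(
    caseid = caseid, primaryid = primaryid, fda_dt = fda_dt, sex = sex,
    age_years = age, occupation_code = occ, reporter_class = cls,
    report_year = as.integer(fda_dt %/% 10000),
    event_date = event_date, therapy_start = therapy_start,
    drugs = drugs, reactions = reactions
  )

  # duplicate injection: clones are strictly newer (later FDA_DT or, for the
  # tie fraction, same FDA_DT with a larger PRIMARYID), so the dedup rule has
  # a unique right answer
  n_dup <- round(config$duplicate_rate * n_total)
  dup_truth <- tibble::tibble(caseid = double(), kept_primaryid = double(),
                              tie = logical())
  if (n_dup > 0) {
    pick <- sort(sample.int(n_total, n_dup))
    clones <- reports[pick, ]
    tie <- runif(n_dup) < config$tie_fraction
    clones$primaryid <- clones$primaryid + 1
    clones$fda_dt[!tie] <- yyyymmdd_plus_days(clones$fda_dt[!tie],
                                              sample(30:120, sum(!tie),
                                                     replace = TRUE))
    clones$report_year <- as.integer(clones$fda_dt %/% 10000)
    dup_truth <- tibble::tibble(caseid = clones$caseid,
                                kept_primaryid = clones$primaryid, tie = tie)
    reports <- as_faers_reports(dplyr::bind_rows(reports, clones))
  }

  per_drug <- lapply(seq_along(config$drug_specs), function(j) {
    spec <- config$drug_specs[[j]]
    sp <- spec$signal_pts
    sp$pt <- normalize_term(sp$pt)
    sp$base_prob <- voc$base_prob[match(sp$pt, voc$pt_norm)]
    sp$cohort_prob <- tune_signal_probability(sp$base_prob, sp$target_ror)
    list(name = spec$name, synonyms = spec$synonyms,
         n_ps_reports = spec$n_ps_reports,
         caseids = caseid[drug_of == j],
         signal_pts = sp, label_pts = normalize_term(spec$label_pts),
         weibull_shape = spec$weibull_shape,
         weibull_scale = spec$weibull_scale)
  })
  names(per_drug) <- vapply(config$drug_specs, function(d) d$name, character(1))

  truth <- structure(list(
    seed = config$seed,
    n_background_reports = n_bg,
    n_base_reports = n_total,
    n_duplicates = n_dup,
    duplicates = dup_truth,
    drugs = per_drug,
    reporter_class = tibble::tibble(caseid = caseid, class = cls)
  ), class = "synthetic_truth")

  list(reports = reports, truth = truth)
}

# normalized reports -> raw FAERS-dialect tables (inverse of build_reports)
reports_to_raw_tables <- function(reports) {
  fmt_num <- function(x) sprintf("%.0f", x)
  demo <- tibble::tibble(
    PRIMARYID = fmt_num(reports$primaryid),
    CASEID = fmt_num(reports$caseid),
    FDA_DT = fmt_num(reports$fda_dt),
    EVENT_DT = reports$event_date,
    AGE = ifelse(is.na(reports$age_years), "", fmt_num(reports$age_years)),
    AGE_COD = ifelse(is.na(reports$age_years), "", "YR"),
    SEX = dplyr::case_match(reports$sex, "male" ~ "M", "female" ~ "F",
                            .default = ""),
    OCCP_COD = ifelse(is.na(reports$occupation_code), "",
                      reports$occupation_code)
  )
  n_drugs <- vapply(reports$drugs, function(d) length(d$name), integer(1))
  drug <- tibble::tibble(
    PRIMARYID = rep(demo$PRIMARYID, n_drugs),
    CASEID = rep(demo$CASEID, n_drugs),
    DRUG_SEQ = as.character(unlist(lapply(n_drugs, seq_len))),
    ROLE_COD = unlist(lapply(reports$drugs, function(d) d$role)),
    DRUGNAME = unlist(lapply(reports$drugs, function(d) d$name))
  )
  n_reac <- lengths(reports$reactions)
  reac <- tibble::tibble(
    PRIMARYID = rep(demo$PRIMARYID, n_reac),
    CASEID = rep(demo$CASEID, n_reac),
    PT = unlist(reports$reactions)
  )
  ther <- tibble::tibble(
    PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID,
    DSG_DRUG_SEQ = "1", START_DT = reports$therapy_start, END_DT = ""
  )
  list(demo = demo, drug = drug, reac = reac, ther = ther)
}

write_faers_table <- function(tab, path, delim) {
  lines <- c(paste(names(tab), collapse = delim),
             do.call(paste, c(as.list(tab), sep = delim)))
  writeLines(lines, path)
  invisible(path)
}

#' Generate and write a synthetic FAERS-style quarter
#'
#' Writes `$`-delimited DEMO/DRUG/REAC/THER files (readable by
#' [read_quarter()]) plus a JSON truth manifest to `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param dialect A [faers_dialect()] used for writing.
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
generate_quarter <- function(config, out_dir, dialect = faers_dialect()) {
  gen <- generate_reports(config)
  raw <- reports_to_raw_tables(gen$reports)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(out_dir, "DEMO.txt"),
             drug = file.path(out_dir, "DRUG.txt"),
             reac = file.path(out_dir, "REAC.txt"),
             ther = file.path(out_dir, "THER.txt"),
             truth = file.path(out_dir, "truth.json"))
  if (config$malformed_row_rate > 0) {
    # drop the last field of a sampled subset of DRUG rows
    n <- nrow(raw$drug)
    bad <- runif(n) < config$malformed_row_rate
    lines <- do.call(paste, c(as.list(raw$drug), sep = dialect$delim))
    lines[bad] <- sub(paste0("\\", dialect$delim, "[^", "\\", dialect$delim,
                             "]*$"), "", lines[bad])
    writeLines(c(paste(names(raw$drug), collapse = dialect$delim), lines),
               paths[["drug"]])
  } else {
    write_faers_table(raw$drug, paths[["drug"]], dialect$delim)
  }
  write_faers_table(raw$demo, paths[["demo"]], dialect$delim)
  write_faers_table(raw$reac, paths[["reac"]], dialect$delim)
  write_faers_table(raw$ther, paths[["ther"]], dialect$delim)
  truth <- gen$truth
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Read a truth manifest written by [generate_quarter()]
#'
#' @param path Path to `truth.json`.
#' @return A `synthetic_truth` list.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$duplicates <- tibble::as_tibble(truth$duplicates)
  truth$reporter_class <- tibble::as_tibble(truth$reporter_class)
  truth$drugs <- lapply(truth$drugs, function(d) {
    d$signal_pts <- tibble::as_tibble(d$signal_pts)
    d
  })
  structure(truth, class = "synthetic_truth")
}
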