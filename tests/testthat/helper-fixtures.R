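# Test fixtures: compact constructors for normalized reports, a small PT->SOC
# map, and writers for FAERS-dialect files.

# Build a faers_reports tibble from per-report scalars. `drug`/`role` give one
# drug row per report (recycled); pass `drugs` directly for multi-drug
# reports. `pts` is a list of character vectors (or one vector recycled).
make_reports <- function(caseid,
                         primaryid = caseid * 100 + 1,
                         fda_dt = 20230101,
                         sex = NA_character_,
                         age = NA_real_,
                         occ = NA_character_,
                         event = "",
                         start = "",
                         drug = "drugx", role = "PS",
                         drugs = NULL,
                         pts = "fatigue") {
  n <- length(caseid)
  rl <- function(x) rep_len(x, n)
  if (is.null(drugs)) {
    drugs <- Map(function(d, r) list(name = d, role = r), rl(drug), rl(role))
    drugs <- unname(drugs)
  }
  if (!is.list(pts)) pts <- list(pts)
  occ <- rl(occ)
  fda_dt <- rl(fda_dt)
  new_reports(
    caseid = caseid, primaryid = rl(primaryid), fda_dt = fda_dt,
    sex = rl(sex), age_years = rl(age), occupation_code = occ,
    reporter_class = classify_reporter(occ),
    report_year = as.integer(fda_dt %/% 10000),
    event_date = rl(event), therapy_start = rl(start),
    drugs = drugs, reactions = rep_len(pts, n)
  )
}

fixture_map <- function() {
  meddra_map(
    pt = c("fatigue", "asthenia", "nausea", "fall", "dizziness",
           "alpha", "beta", "gamma"),
    soc = c("General disorders", "General disorders",
            "Gastrointestinal disorders",
            "Injury and procedural complications",
            "Nervous system disorders", "SOC A", "SOC A", "SOC B")
  )
}

# write a tiny comma-dialect quarter; each argument is a character vector of
# pre-joined data lines (without header)
write_mini_quarter <- function(dir, demo, drug, reac, ther, delim = ",") {
  hdr <- faers_schemas()
  join <- function(cols) paste(cols, collapse = delim)
  paths <- list(demo = file.path(dir, "demo.txt"),
                drug = file.path(dir, "drug.txt"),
                reac = file.path(dir, "reac.txt"),
                ther = file.path(dir, "ther.txt"))
  writeLines(c(join(hdr$demo), demo), paths$demo)
  writeLines(c(join(hdr$drug), drug), paths$drug)
  writeLines(c(join(hdr$reac), reac), paths$reac)
  writeLines(c(join(hdr$ther), ther), paths$ther)
  paths
}

mini_sim_config <- function(seed, n_background = 300, n_ps = 40, ...) {
  sim_config(
    n_background_reports = n_background, seed = seed,
    drug_specs = list(drug_spec(
      "sirnafirst", c("firstpattro", "sirnafirst sodium"), n_ps,
      signal_pts = tibble::tibble(pt = "fatigue", target_ror = 8),
      label_pts = c("fatigue", "arthralgia"),
      weibull_shape = 0.81, weibull_scale = 325.5)),
    ...
  )
}
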