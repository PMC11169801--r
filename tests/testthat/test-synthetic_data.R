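test_that("signal probability tuning reproduces the odds identity", {
  expect_equal(tune_signal_probability(0.01, 1), 0.01)
  expect_equal(tune_signal_probability(0.5, 1), 0.5)
  expect_equal(tune_signal_probability(0.01, 8), 0.0748, tolerance = 1e-3)
  # p always stays a probability, and the odds ratio is exact
  set.seed(2)
  q <- runif(50, 0.001, 0.6)
  r <- 10^runif(50, -1, 2)
  p <- tune_signal_probability(q, r)
  expect_true(all(p > 0 & p < 1))
  expect_equal((p / (1 - p)) / (q / (1 - q)), r)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- mini_sim_config(seed = 33, n_background = 120, n_ps = 15)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_quarter(cfg, d1)
  g2 <- generate_quarter(cfg, d2)
  for (nm in c("demo", "drug", "reac", "ther", "truth")) {
    expect_identical(readLines(g1$paths[[nm]]), readLines(g2$paths[[nm]]))
  }
  # a different seed changes the data
  g3 <- generate_quarter(mini_sim_config(seed = 34, n_background = 120,
                                         n_ps = 15),
                         withr::local_tempdir())
  expect_false(identical(readLines(g1$paths[["demo"]]),
                         readLines(g3$paths[["demo"]])))
})

test_that("duplicate injection matches the configured rate and dedups away", {
  cfg <- mini_sim_config(seed = 55, n_background = 900, n_ps = 100,
                         duplicate_rate = 0.1)
  gen <- generate_reports(cfg)
  expect_equal(gen$truth$n_duplicates, 100)
  expect_equal(nrow(gen$reports), 1100)
  expect_equal(sum(duplicated(gen$reports$caseid)), 100)
  dd <- deduplicate(gen$reports)
  expect_equal(nrow(dd), 1000)
  expect_false(anyDuplicated(dd$caseid) > 0)
  # ties on fda_dt were injected to exercise the primaryid tie-break
  expect_gt(sum(gen$truth$duplicates$tie), 0)
  expect_equal(dd$primaryid[match(gen$truth$duplicates$caseid, dd$caseid)],
               gen$truth$duplicates$kept_primaryid)
})

test_that("generated files re-ingest with zero rejects and full fidelity", {
  cfg <- mini_sim_config(seed = 8, n_background = 200, n_ps = 30)
  out <- withr::local_tempdir()
  gq <- generate_quarter(cfg, out)
  rq <- read_quarter(gq$paths[["demo"]], gq$paths[["drug"]],
                     gq$paths[["reac"]], gq$paths[["ther"]])
  expect_equal(nrow(rq$rejects), 0)
  expect_equal(nrow(rq$orphans), 0)
  expect_equal(nrow(rq$demo), nrow(generate_reports(cfg)$reports))
  # with malformation injection on, rejects appear and are attributed
  cfg_bad <- mini_sim_config(seed = 8, n_background = 200, n_ps = 30,
                             malformed_row_rate = 0.1)
  gq2 <- generate_quarter(cfg_bad, withr::local_tempdir())
  rq2 <- read_quarter(gq2$paths[["demo"]], gq2$paths[["drug"]],
                      gq2$paths[["reac"]], gq2$paths[["ther"]])
  expect_gt(nrow(rq2$rejects), 0)
  expect_true(all(rq2$rejects$reason == "field_count"))
  expect_true(all(rq2$rejects$table == "drug"))
})

test_that("the truth manifest round-trips through JSON", {
  cfg <- mini_sim_config(seed = 12, n_background = 80, n_ps = 12)
  out <- withr::local_tempdir()
  gq <- generate_quarter(cfg, out)
  tr <- read_truth(gq$paths[["truth"]])
  expect_equal(tr$n_background_reports, 80)
  expect_equal(tr$drugs$sirnafirst$n_ps_reports, 12)
  expect_equal(tr$drugs$sirnafirst$signal_pts$pt, "fatigue")
  expect_equal(tr$drugs$sirnafirst$signal_pts$target_ror, 8)
  expect_equal(length(tr$drugs$sirnafirst$caseids), 12)
})

test_that("a signal PT outside the vocabulary is fatal", {
  cfg <- sim_config(
    n_background_reports = 50, seed = 1,
    drug_specs = list(drug_spec(
      "sirnafirst", character(), 10,
      signal_pts = tibble::tibble(pt = "no such pt", target_ror = 3))))
  expect_error(generate_reports(cfg), class = "unknown_signal_pt")
})

test_that("planted cohort signal frequencies track the tuned probability", {
  cfg <- mini_sim_config(seed = 99, n_background = 2000, n_ps = 500,
                         duplicate_rate = 0)
  gen <- generate_reports(cfg)
  tr <- gen$truth$drugs$sirnafirst
  in_cohort <- gen$reports$caseid %in% tr$caseids
  has_pt <- vapply(gen$reports$reactions,
                   function(r) "fatigue" %in% normalize_term(r), logical(1))
  p_hat <- mean(has_pt[in_cohort])
  q_hat <- mean(has_pt[!in_cohort])
  expect_equal(p_hat, tr$signal_pts$cohort_prob, tolerance = 0.25)
  expect_equal(q_hat, tr$signal_pts$base_prob, tolerance = 0.35)
})

test_that("YAML simulation configs load with defaults filled in", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_background_reports: 120",
    "duplicate_rate: 0.05",
    "seed: 4",
    "drugs:",
    "  - name: sirnafirst",
    "    synonyms: [firstpattro]",
    "    n_ps_reports: 15",
    "    signal_pts:",
    "      - {pt: fatigue, target_ror: 6}",
    "    weibull_shape: 0.9",
    "    weibull_scale: 200"
  ), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_background_reports, 120)
  expect_equal(cfg$drug_specs[[1]]$signal_pts$target_ror, 6)
  expect_equal(cfg$seed, 4)
  cfg2 <- read_sim_config(f, seed = 99)
  expect_equal(cfg2$seed, 99)
  gen <- generate_reports(cfg)
  expect_equal(nrow(gen$reports), 135 + gen$truth$n_duplicates)
})
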