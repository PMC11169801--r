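test_that("deduplication keeps the latest FDA_DT, then the largest PRIMARYID", {
  reports <- make_reports(
    caseid = c(2751007, 2751007, 2720901, 2720901, 1),
    primaryid = c(51321061, 51364244, 26542012, 27532429, 100),
    fda_dt = c(40064207, 40064345, 40064112, 40064112, 20230101)
  )
  kept <- deduplicate(reports)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$primaryid[kept$caseid == 2751007], 51364244)
  expect_equal(kept$primaryid[kept$caseid == 2720901], 27532429)
  expect_equal(kept$primaryid[kept$caseid == 1], 100)
})

test_that("deduplication is idempotent and order-independent", {
  gen <- generate_reports(mini_sim_config(seed = 3, n_background = 200,
                                          n_ps = 30))
  dd <- deduplicate(gen$reports)
  expect_false(anyDuplicated(dd$caseid) > 0)
  expect_equal(as.data.frame(deduplicate(dd)), as.data.frame(dd))
  for (s in 1:3) {
    set.seed(s)
    perm <- gen$reports[sample(nrow(gen$reports)), ]
    expect_equal(as.data.frame(deduplicate(perm)), as.data.frame(dd))
  }
  # injected duplicates resolve to the truth manifest's surviving version
  tr <- gen$truth$duplicates
  expect_gt(nrow(tr), 0)
  expect_equal(dd$primaryid[match(tr$caseid, dd$caseid)], tr$kept_primaryid)
})

test_that("exact ties on fda_dt and primaryid keep first seen with a warning", {
  reports <- make_reports(caseid = c(7, 7), primaryid = c(70, 70),
                          fda_dt = c(20230101, 20230101),
                          pts = list("fatigue", "nausea"))
  expect_warning(kept <- deduplicate(reports), "ties")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$reactions[[1]], "fatigue")
})

test_that("drug matching is synonym-, case- and suffix-robust", {
  q <- drug_query("patisiran", c("ALN-TTR02", "onpattro", "patisiran sodium"))
  expect_true(match_drug("ONPATTRO", q))
  expect_true(match_drug("PATISIRAN SODIUM.", q))
  expect_true(match_drug("  Patisiran   Sodium 10 MG", q))
  expect_true(match_drug("ALN-TTR02", q))
  expect_false(match_drug("TAFAMIDIS", q))
  expect_false(match_drug("NOTPATISIRANIC ACID", q))
  expect_equal(match_drug(c("onpattro", "aspirin"), q), c(TRUE, FALSE))
})

test_that("primary-suspect cohort keeps only PS-role matches", {
  q <- drug_query("sirnafirst", "firstpattro")
  reports <- make_reports(
    caseid = 1:3,
    drugs = list(
      list(name = "SIRNAFIRST", role = "SS"),              # role excluded
      list(name = "FIRSTPATTRO", role = "PS"),             # included
      list(name = c("ASPIRIN", "SIRNAFIRST"), role = c("PS", "C")) # wrong drug is PS
    )
  )
  cohort <- select_ps_cohort(reports, q)
  expect_equal(cohort$caseid, 2)
})

test_that("planted PS cohorts are recovered exactly from the truth manifest", {
  gen <- generate_reports(mini_sim_config(seed = 21, n_background = 960,
                                          n_ps = 40))
  dd <- deduplicate(gen$reports)
  expect_equal(nrow(dd), 1000)
  cohort <- select_ps_cohort(dd, drug_query("sirnafirst",
                                            c("firstpattro",
                                              "sirnafirst sodium")))
  expect_equal(nrow(cohort), 40)
  expect_setequal(cohort$caseid, gen$truth$drugs[[1]]$caseids)
  # a query for unrelated names selects a disjoint cohort
  other <- select_ps_cohort(dd, drug_query("metformin"))
  expect_length(intersect(other$caseid, cohort$caseid), 0)
})

test_that("reporter classification partitions codes into three classes", {
  expect_equal(classify_reporter(c("MD", "PH", "OT", "HP")),
               rep("medical", 4))
  expect_equal(classify_reporter(c("CN", "LW")), rep("non_medical", 2))
  expect_equal(classify_reporter(c(NA, "", "RN", "md ")),
               c("unknown", "unknown", "unknown", "medical"))
  # configurable code sets
  expect_equal(classify_reporter("RN", medical_codes = "RN"), "medical")
  cls <- classify_reporter(sample(c("MD", "CN", NA, "zz"), 50, replace = TRUE))
  expect_equal(sum(cls == "medical") + sum(cls == "non_medical") +
                 sum(cls == "unknown"), 50)
})

test_that("age conversion applies unit codes and range checks", {
  expect_equal(age_to_years(c(65, 6, 24), c("YR", "DEC", "MON")),
               c(65, 60, 2))
  expect_equal(age_to_years(104.36, "WK"), 2, tolerance = 1e-4)
  expect_equal(age_to_years(730.5, "DY"), 2)
  expect_equal(age_to_years(8766, "HR"), 1)
  expect_true(is.na(age_to_years(NA, "YR")))
  expect_true(is.na(age_to_years(5, "XX")))
  expect_warning(out <- age_to_years(300, "YR"), "outside")
  expect_true(is.na(out))
})

test_that("PT to SOC mapping is case-insensitive with an UNMAPPED sentinel", {
  map <- fixture_map()
  expect_equal(map_pt_to_soc("Fatigue", map), "General disorders")
  expect_equal(map_pt_to_soc("FaTiGuE", map), map_pt_to_soc("fatigue", map))
  expect_equal(map_pt_to_soc("no such term", map), "UNMAPPED")
  # a PT mapped to two SOCs is rejected at construction
  expect_error(meddra_map(c("x", "X"), c("SOC A", "SOC B")),
               class = "meddra_map_conflict")
  # delimited round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pt\tsoc", "fatigue\tGeneral disorders"), f)
  m2 <- read_meddra_map(f)
  expect_equal(map_pt_to_soc("FATIGUE", m2), "General disorders")
})
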