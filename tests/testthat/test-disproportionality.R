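# independent odds-ratio oracle: structured differently from the package
# implementation (odds of exposure in each group, CI via qnorm-scaled SE)
oracle_or <- function(a, b, c, d) {
  odds_cohort <- a / b
  odds_background <- c / d
  est <- odds_cohort / odds_background
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- 1.96
  list(est = est, lo = est * exp(-z * se), hi = est * exp(z * se))
}

test_that("contingency cells count unique (report, term) pairs", {
  cohort <- make_reports(caseid = 1:2, pts = "X")
  background <- make_reports(caseid = 3:10,
                             pts = as.list(c("X", "X", "X", rep("Y", 5))))
  ct <- build_contingency(cohort, background, "X")
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(2, 0, 3, 5))
  # a PT listed twice on one report counts once
  dup <- make_reports(caseid = 1, pts = list(c("X", "x", "X ")))
  expect_equal(build_contingency(dup, background, "X")$a, 1)
  # empty cohort
  ct0 <- build_contingency(cohort[0, ], background, "X")
  expect_equal(c(ct0$a, ct0$b), c(0, 0))
  # term absent everywhere is flagged
  expect_true(build_contingency(cohort, background, "Z")$flagged)
})

test_that("a report contributes once per SOC no matter how many PTs map there", {
  map <- fixture_map()
  cohort <- make_reports(caseid = 1, pts = list(c("alpha", "beta")))  # both SOC A
  background <- make_reports(caseid = 2:4, pts = as.list(c("alpha", "gamma", "gamma")))
  ct <- build_contingency(cohort, background, "SOC A", level = "SOC",
                          meddra_map = map)
  expect_equal(ct$a, 1)
  expect_equal(ct$c, 1)
})

test_that("ror matches frozen worked examples and flags zero cells", {
  even <- ror(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(even$ror, 1)
  expect_lt(even$ci_low, 1)
  expect_gt(even$ci_high, 1)

  r <- ror(list(a = 20, b = 80, c = 100, d = 9800))
  expect_equal(r$ror, 24.5)
  expect_equal(r$ci_low, 14.447996, tolerance = 1e-6)
  expect_equal(r$ci_high, 41.545555, tolerance = 1e-6)

  sparse <- ror(list(a = 2, b = 998, c = 2, d = 8998))
  expect_equal(sparse$ror, 9.016032, tolerance = 1e-6)
  orc <- oracle_or(2, 998, 2, 8998)
  expect_equal(sparse$ci_low, orc$lo)

  zero <- ror(list(a = 0, b = 10, c = 5, d = 100))
  expect_true(zero$incalculable)
  expect_true(is.na(zero$ror))
})

test_that("ror equals the independent oracle over a cell grid", {
  grid <- expand.grid(a = c(1, 2, 7, 23, 50), b = c(1, 3, 19, 50),
                      c = c(1, 5, 31, 50), d = c(1, 11, 42, 50))
  r <- faersmine:::ror_stats(grid$a, grid$b, grid$c, grid$d)
  orc <- oracle_or(grid$a, grid$b, grid$c, grid$d)
  expect_equal(r$ror, orc$est, tolerance = 1e-12)
  expect_equal(r$ci_low, orc$lo, tolerance = 1e-12)
  expect_equal(r$ci_high, orc$hi, tolerance = 1e-12)
})

test_that("swapping the 2x2 rows inverts the ROR and its CI", {
  set.seed(4)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    r1 <- ror(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]))
    r2 <- ror(list(a = cells[3], b = cells[4], c = cells[1], d = cells[2]))
    expect_equal(r2$ror, 1 / r1$ror)
    expect_equal(r2$ci_low, 1 / r1$ci_high)
    expect_equal(r2$ci_high, 1 / r1$ci_low)
  }
})

test_that("increasing a with b, c, d fixed strictly increases the ROR", {
  rors <- faersmine:::ror_stats(1:30, 40, 25, 900)$ror
  expect_true(all(diff(rors) > 0))
})

test_that("the signal criterion needs ci_low > 1 and at least two reports", {
  expect_true(signal_criteria(list(ci_low = 1.2, n = 5)))
  expect_false(signal_criteria(list(ci_low = 1.2, n = 1)))
  expect_false(signal_criteria(list(ci_low = 0.99, n = 100)))
  expect_false(signal_criteria(list(ci_low = NA_real_, n = 10,
                                    incalculable = TRUE)))
})

test_that("top_terms ranks by N with alphabetical ties and honours exclusions", {
  cohort <- make_reports(
    caseid = 1:30,
    pts = as.list(c(rep("alpha", 30)))
  )
  cohort$reactions <- lapply(seq_len(30), function(i) {
    c("alpha", if (i <= 20) "beta", if (i <= 10) "gamma")
  })
  background <- make_reports(caseid = 101:150, pts = "delta")
  top <- top_terms(cohort, background, k = 2, exclusion_list = "gamma")
  expect_equal(top$term, c("alpha", "beta"))
  expect_equal(top$n, c(30, 20))
  # k beyond the distinct terms returns everything left
  all_terms <- top_terms(cohort, background, k = 99,
                         exclusion_list = "gamma")
  expect_setequal(all_terms$term, c("alpha", "beta"))
  # equal N resolves alphabetically
  tie <- make_reports(caseid = 1:4, pts = as.list(c("zeta", "eta", "zeta", "eta")))
  expect_equal(top_terms(tie, background, k = 2)$term, c("eta", "zeta"))
})

test_that("expectedness splits significant signals by the label term list", {
  res <- tibble::tibble(
    term = c("vitamin a decreased", "weird new term", "rare thing"),
    level = "PT", n = c(10, 8, 1),
    ror = c(3, 4, 2), ci_low = c(1.5, 2, 0.5), ci_high = c(6, 8, 8),
    incalculable = FALSE, significant = c(TRUE, TRUE, FALSE)
  )
  out <- classify_expectedness(res, c("Vitamin A decreased", "muscle spasms"))
  expect_equal(out$expectedness,
               c("labeled", "unexpected", "not_significant"))
})

test_that("cross-drug overlap intersects labeled and unexpected sets", {
  mk <- function(terms, expectedness) {
    tibble::tibble(term = terms, expectedness = expectedness)
  }
  a <- mk(c("x", "y", "l1"), c("unexpected", "unexpected", "labeled"))
  b <- mk(c("y", "z", "l1"), c("unexpected", "unexpected", "labeled"))
  ov <- cross_drug_overlap(list(A = a, B = b))
  expect_equal(ov$common_unexpected, "y")
  expect_equal(ov$common_labeled, "l1")
  c_ <- mk("q", "unexpected")
  expect_length(cross_drug_overlap(list(a, b, c_))$common_unexpected, 0)
  expect_equal(cross_drug_overlap(list(a, a, a))$common_unexpected,
               c("x", "y"))
})

test_that("term lists load with comments stripped and signals export cleanly", {
  f <- withr::local_tempfile()
  writeLines(c("# outcome terms", "", "Death", "  Hospitalisation  "), f)
  expect_equal(read_term_list(f), c("death", "hospitalisation"))
  cohort <- make_reports(caseid = 1:5, pts = "alpha")
  background <- make_reports(caseid = 11:40,
                             pts = as.list(rep(c("alpha", "beta"), 15)))
  res <- top_terms(cohort, background, k = 5)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(res, out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(back$term, res$term)
  expect_equal(back$n, res$n)
})
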