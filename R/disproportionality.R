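# Reporting odds ratio (ROR) disproportionality analysis at PT and SOC level.
#
# The counting unit throughout is the unique (report, term) pair: a PT listed
# twice on one report counts once, and at SOC level a report contributes once
# per SOC regardless of how many of its PTs map there.

# unique normalized terms carried by each report at the requested level
report_terms <- function(reports, level = c("PT", "SOC"), meddra_map = NULL) {
  level <- match.arg(level)
  if (level == "SOC" && is.null(meddra_map)) {
    abort_faersmine("SOC-level analysis requires a meddra_map", "missing_meddra_map")
  }
  lapply(reports$reactions, function(pts) {
    terms <- normalize_term(pts)
    if (level == "SOC") terms <- normalize_term(map_pt_to_soc(terms, meddra_map))
    unique(terms)
  })
}

count_term <- function(term_lists, term) {
  sum(vapply(term_lists, function(t) term %in% t, logical(1)))
}

#' Build the 2x2 contingency table for one drug-term pair
#'
#' Cell `a` counts cohort reports carrying the term, `b` the remaining cohort
#' reports, `c` background reports carrying the term and `d` the remaining
#' background reports. The background is the comparator set of reports (by
#' default, everything in the loaded window outside the cohort).
#'
#' @param cohort,background `faers_reports` tibbles; disjoint report sets.
#' @param term The PT or SOC of interest (any case).
#' @param level `"PT"` or `"SOC"`.
#' @param meddra_map A [meddra_map()]; required at SOC level.
#' @return A `contingency_table` list with fields `a`, `b`, `c`, `d`, `term`,
#'   `level` and `flagged` (TRUE when the term occurs in neither set).
#' @export
build_contingency <- function(cohort, background, term,
                              level = c("PT", "SOC"), meddra_map = NULL) {
  level <- match.arg(level)
  stopifnot(nzchar(term))
  key <- normalize_term(term)
  if (level == "SOC") key <- normalize_term(key)
  a <- count_term(report_terms(cohort, level, meddra_map), key)
  c_ <- count_term(report_terms(background, level, meddra_map), key)
  structure(list(a = a, b = nrow(cohort) - a, c = c_,
                 d = nrow(background) - c_,
                 term = key, level = level, flagged = (a + c_ == 0L)),
            class = "contingency_table")
}

# Vectorized ROR with Wald 95% CI on the log scale. Any zero cell makes the
# estimate incalculable; no continuity correction is applied.
ror_stats <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  incalculable <- a <= 0 | b <= 0 | c <= 0 | d <= 0
  est <- rep(NA_real_, length(a))
  lo <- hi <- est
  ok <- !incalculable
  if (any(ok)) {
    est[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
    se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
    lo[ok] <- exp(log(est[ok]) - 1.96 * se)
    hi[ok] <- exp(log(est[ok]) + 1.96 * se)
  }
  tibble::tibble(ror = est, ci_low = lo, ci_high = hi,
                 incalculable = incalculable)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a d)/(b c); the 95% CI is the Wald interval
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). A table with any zero
#' cell is flagged incalculable rather than continuity-corrected: the
#' downstream signal criterion requires at least two co-reports anyway.
#'
#' @param table A `contingency_table` from [build_contingency()], or a list
#'   with fields `a`, `b`, `c`, `d`.
#' @return List with `ror`, `ci_low`, `ci_high`, `incalculable`.
#' @export
#' @examples
#' ror(list(a = 20, b = 80, c = 100, d = 9800))
ror <- function(table) {
  s <- ror_stats(table$a, table$b, table$c, table$d)
  list(ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
       incalculable = s$incalculable)
}

#' Signal criterion: lower CI bound above 1 and at least two reports
#'
#' A drug-term pair is a significant signal when the lower bound of the ROR
#' 95% CI exceeds 1 and the number of co-reports N is at least 2.
#' Incalculable results are never significant.
#'
#' @param result A list or one-row tibble with fields `ci_low`, `n` and
#'   optionally `incalculable`.
#' @return Logical.
#' @export
signal_criteria <- function(result) {
  inc <- isTRUE(result$incalculable) | is.na(result$ci_low)
  !inc & result$ci_low > 1 & result$n >= 2
}

#' Rank the most-reported terms and attach ROR signals
#'
#' Counts each term's cohort reports (unique per report), removes terms on
#' the exclusion list, ranks by N descending with alphabetical tie-break, and
#' computes the ROR, CI and significance flag for the top `k`.
#'
#' @param cohort,background Disjoint `faers_reports` tibbles.
#' @param level `"PT"` or `"SOC"`.
#' @param k Maximum number of terms returned.
#' @param exclusion_list Character vector of terms to drop before ranking
#'   (outcome terms, injection/infusion terms, disease symptoms, ...).
#' @param meddra_map A [meddra_map()]; required at SOC level.
#' @return A `signal_results` tibble: `term`, `level`, `n`, `ror`, `ci_low`,
#'   `ci_high`, `incalculable`, `significant`.
#' @export
top_terms <- function(cohort, background, level = c("PT", "SOC"), k = 50,
                      exclusion_list = character(), meddra_map = NULL) {
  level <- match.arg(level)
  stopifnot(k >= 1)
  terms_cohort <- report_terms(cohort, level, meddra_map)
  counts <- table(unlist(terms_cohort))
  tb <- tibble::tibble(term = as.character(names(counts)),
                       n = as.integer(counts))
  tb <- tb[!tb$term %in% normalize_term(exclusion_list), ]
  tb <- tb[order(-tb$n, tb$term), ]
  tb <- head(tb, k)
  terms_bg <- report_terms(background, level, meddra_map)
  a <- tb$n
  c_ <- vapply(tb$term, function(t) count_term(terms_bg, t), integer(1))
  s <- ror_stats(a, nrow(cohort) - a, c_, nrow(background) - c_)
  out <- dplyr::bind_cols(
    tibble::tibble(term = tb$term, level = level, n = a), s)
  out$significant <- !out$incalculable & out$ci_low > 1 & out$n >= 2
  class(out) <- c("signal_results", class(out))
  out
}

#' Classify significant signals as label-expected or unexpected
#'
#' A significant term already on the drug's label is `labeled`; a significant
#' term absent from the label is an `unexpected` signal; everything else is
#' `not_significant`.
#'
#' @param results A `signal_results` tibble.
#' @param label_terms Character vector of PTs on the drug's current label.
#' @return `results` with an `expectedness` column added.
#' @export
classify_expectedness <- function(results, label_terms) {
  on_label <- results$term %in% normalize_term(label_terms)
  results$expectedness <- dplyr::case_when(
    results$significant & on_label ~ "labeled",
    results$significant & !on_label ~ "unexpected",
    TRUE ~ "not_significant"
  )
  results
}

#' Signals shared across drugs
#'
#' Intersects the labeled-significant and unexpected-significant term sets of
#' two or more drugs' signal tables.
#'
#' @param per_drug_results Named list (length >= 2) of `signal_results`
#'   tibbles carrying an `expectedness` column.
#' @return List with character vectors `common_labeled`, `common_unexpected`.
#' @export
cross_drug_overlap <- function(per_drug_results) {
  stopifnot(length(per_drug_results) >= 2)
  pick <- function(res, what) sort(res$term[res$expectedness == what])
  list(
    common_labeled = Reduce(intersect,
                            lapply(per_drug_results, pick, "labeled")),
    common_unexpected = Reduce(intersect,
                               lapply(per_drug_results, pick, "unexpected"))
  )
}

#' Read a one-term-per-line list (exclusion or label terms)
#'
#' Lines starting with `#` and blank lines are ignored; terms are normalized.
#'
#' @param path Text file path.
#' @return Character vector of normalized terms.
#' @export
read_term_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  normalize_term(lines)
}

#' Write a signal table as delimited text
#'
#' @param results A `signal_results` tibble.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path, na = "NA")
  invisible(path)
}

#' Forest plot of ROR signals
#'
#' Terms ordered by report count; points at the ROR with horizontal 95% CI
#' bars on a log axis, the null value 1 marked.
#'
#' @param results A `signal_results` tibble (calculable rows are plotted).
#' @return A ggplot object.
#' @export
plot_signals <- function(results) {
  df <- tibble::as_tibble(results)
  df <- df[!df$incalculable, ]
  df$term <- factor(df$term, levels = rev(df$term[order(-df$n, df$term)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
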