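# Clinical-characteristics summary of a report cohort (sex, age band,
# reporter type, reporting year), in the style of a published Table of
# spontaneous-report demographics.

age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "missing",
    age_years < 18 ~ "<18",
    age_years <= 65 ~ "18-65",    # boundary ages 18 and 65 fall in the closed band
    TRUE ~ ">65"
  )
}

count_breakdown <- function(x, levels, total) {
  x <- factor(x, levels = levels)
  cnt <- as.integer(table(x))
  tibble::tibble(
    category = levels,
    count = cnt,
    percent = if (total > 0) round_half_up(100 * cnt / total, 1) else rep(NA_real_, length(cnt))
  )
}

#' Summarize the clinical characteristics of a cohort
#'
#' Produces the standard descriptive breakdowns of a spontaneous-report
#' cohort: sex, age band (<18, 18-65, >65), reporter type and reporting
#' year, each with a missing category so counts sum to the cohort total.
#' Percentages are computed on the full cohort total (missing included in the
#' denominator) and rounded half-up to one decimal, matching how such tables
#' are printed.
#'
#' @param cohort A deduplicated `faers_reports` tibble.
#' @return A `cohort_summary` list: `total` plus tibbles `by_sex`,
#'   `by_age_band`, `by_reporter`, `by_year`, each with columns
#'   `category`, `count`, `percent`.
#' @export
summarize_cohort <- function(cohort) {
  total <- nrow(cohort)
  if (total == 0L) {
    empty <- tibble::tibble(category = character(), count = integer(),
                            percent = double())
    return(structure(list(total = 0L, by_sex = empty, by_age_band = empty,
                          by_reporter = empty, by_year = empty),
                     class = "cohort_summary"))
  }
  sex <- ifelse(is.na(cohort$sex), "missing", cohort$sex)
  reporter <- ifelse(is.na(cohort$reporter_class) |
                       cohort$reporter_class == "unknown",
                     "missing", cohort$reporter_class)
  year <- ifelse(is.na(cohort$report_year), "missing",
                 as.character(cohort$report_year))
  year_levels <- c(sort(unique(year[year != "missing"])),
                   if (any(year == "missing")) "missing")
  structure(list(
    total = total,
    by_sex = count_breakdown(sex, c("female", "male", "missing"), total),
    by_age_band = count_breakdown(age_band(cohort$age_years),
                                  c("<18", "18-65", ">65", "missing"), total),
    by_reporter = count_breakdown(reporter,
                                  c("medical", "non_medical", "missing"), total),
    by_year = count_breakdown(year, year_levels, total)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> total reports: %d\n", x$total))
  for (nm in c("by_sex", "by_age_band", "by_reporter", "by_year")) {
    cat("\n", sub("by_", "", nm), ":\n", sep = "")
    tb <- x[[nm]]
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("  %-12s %6d (%.1f%%)\n", tb$category[i], tb$count[i],
                  tb$percent[i]))
    }
  }
  invisible(x)
}

#' Write a cohort summary as delimited text
#'
#' @param summary A `cohort_summary`.
#' @param path Output path (tab-separated: breakdown, category, count,
#'   percent).
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  rows <- purrr::imap(summary[c("by_sex", "by_age_band", "by_reporter",
                                "by_year")], function(tb, nm) {
    dplyr::mutate(tb, breakdown = sub("^by_", "", nm), .before = 1)
  })
  out <- dplyr::bind_rows(
    tibble::tibble(breakdown = "total", category = "total",
                   count = summary$total, percent = 100),
    dplyr::bind_rows(rows)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
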