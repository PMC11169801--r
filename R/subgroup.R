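# Reporter-type subgroup analysis: stratify signal mining by whether the
# reporter was a medical professional and compare the significant-term sets.

#' Stratified signal mining by reporter type
#'
#' Splits the cohort into medical-professional and non-medical-professional
#' strata (unknown reporters are excluded from both), runs [top_terms()]
#' within each stratum with the same ranking depth and criteria, and returns
#' the common and stratum-unique significant-term sets. The comparator
#' (background) is restricted to the same reporter class as the stratum so
#' that each stratum's ROR is internally consistent; set
#' `stratify_background = FALSE` to compare every stratum against the full
#' background instead.
#'
#' @param cohort,background Disjoint `faers_reports` tibbles with
#'   `reporter_class` assigned.
#' @param level `"PT"` or `"SOC"`.
#' @param k Ranking depth passed to [top_terms()].
#' @param exclusion_list Terms removed before ranking.
#' @param meddra_map A [meddra_map()]; required at SOC level.
#' @param stratify_background Restrict the comparator to the stratum's
#'   reporter class (default TRUE).
#' @return A `subgroup_comparison` list: `stratum_results` (named list of
#'   `signal_results`), `common`, `unique_medical`, `unique_non_medical`.
#' @export
subgroup_signals <- function(cohort, background, level = "PT", k = 50,
                             exclusion_list = character(), meddra_map = NULL,
                             stratify_background = TRUE) {
  strata <- c("medical", "non_medical")
  results <- lapply(setNames(strata, strata), function(cls) {
    sub_cohort <- cohort[cohort$reporter_class == cls, ]
    sub_bg <- if (stratify_background) {
      background[background$reporter_class == cls, ]
    } else {
      background
    }
    if (nrow(sub_cohort) == 0L) {
      message("subgroup_signals: no ", cls, " reports in the cohort")
      res <- top_terms(cohort[0, ], sub_bg, level = level, k = k,
                       exclusion_list = exclusion_list,
                       meddra_map = meddra_map)
      return(res)
    }
    top_terms(sub_cohort, sub_bg, level = level, k = k,
              exclusion_list = exclusion_list, meddra_map = meddra_map)
  })
  sig <- lapply(results, function(r) sort(r$term[r$significant]))
  structure(list(
    stratum_results = results,
    common = intersect(sig$medical, sig$non_medical),
    unique_medical = setdiff(sig$medical, sig$non_medical),
    unique_non_medical = setdiff(sig$non_medical, sig$medical)
  ), class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat("<subgroup_comparison>\n")
  cat("  common significant signals:", length(x$common), "\n")
  cat("  unique to medical reporters:", length(x$unique_medical), "\n")
  cat("  unique to non-medical reporters:", length(x$unique_non_medical), "\n")
  invisible(x)
}

#' Write a subgroup comparison as delimited text
#'
#' One row per significant term with its stratum pattern (common /
#' medical_only / non_medical_only) and the per-stratum N, ROR and CI.
#'
#' @param comparison A `subgroup_comparison`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_subgroup_comparison <- function(comparison, path) {
  pattern_of <- function(term) {
    if (term %in% comparison$common) "common"
    else if (term %in% comparison$unique_medical) "medical_only"
    else "non_medical_only"
  }
  terms <- sort(unique(c(comparison$common, comparison$unique_medical,
                         comparison$unique_non_medical)))
  per_stratum <- purrr::imap(comparison$stratum_results, function(res, cls) {
    res <- tibble::as_tibble(res)[c("term", "n", "ror", "ci_low", "ci_high")]
    names(res)[-1] <- paste0(cls, "_", names(res)[-1])
    res
  })
  out <- tibble::tibble(term = terms,
                        pattern = vapply(terms, pattern_of, character(1)))
  for (tb in per_stratum) out <- dplyr::left_join(out, tb, by = "term")
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
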