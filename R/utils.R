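# Shared helpers: term/name normalization and printed-style rounding.

#' Normalize a term or drug name for matching
#'
#' Trims leading/trailing whitespace, case-folds to lower case and collapses
#' internal whitespace runs to a single space. All PT, SOC and drug-name
#' comparisons in the package go through this normalization so that verbatim
#' FAERS spellings ("FaTiGuE ", "PATISIRAN  SODIUM.") compare as intended.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_term(c("  FaTiGuE ", "Pain  in   extremity"))
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` uses round-half-even; published clinical tables round half
#' up, so percentage output uses this rule.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop with a classed condition so callers/tests can match on class
abort_faersmine <- function(msg, class) {
  rlang::abort(msg, class = c(class, "faersmine_error"))
}
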