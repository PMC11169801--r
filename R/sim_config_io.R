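# YAML front end for the simulator, used by inst/scripts/simulate-quarter.R.

#' Read a simulation configuration from YAML
#'
#' The file may set any [sim_config()] argument; drugs are given as a `drugs`
#' list whose entries hold the [drug_spec()] fields, with `signal_pts` as a
#' list of `{pt, target_ror, stratum}` records. Omitted fields fall back to
#' the package defaults.
#'
#' @param path YAML file path.
#' @param seed Optional integer overriding the file's seed.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  specs <- if (is.null(y$drugs)) default_drug_specs() else {
    lapply(y$drugs, function(d) {
      drug_spec(
        name = d$name,
        synonyms = as.character(d$synonyms %||% character()),
        n_ps_reports = d$n_ps_reports,
        signal_pts = dplyr::bind_rows(lapply(d$signal_pts, tibble::as_tibble)),
        label_pts = as.character(d$label_pts %||% character()),
        weibull_shape = d$weibull_shape %||% 1,
        weibull_scale = d$weibull_scale %||% 180
      )
    })
  }
  defaults <- formals(sim_config)
  take <- function(nm, coerce = identity) {
    if (!is.null(y[[nm]])) coerce(y[[nm]]) else eval(defaults[[nm]])
  }
  sim_config(
    n_background_reports = take("n_background_reports"),
    drug_specs = specs,
    duplicate_rate = take("duplicate_rate"),
    tie_fraction = take("tie_fraction"),
    missingness = take("missingness", as.list),
    date_precision_mix = take("date_precision_mix", unlist),
    reporter_mix = take("reporter_mix", unlist),
    year_range = take("year_range", function(x) as.integer(unlist(x))),
    malformed_row_rate = take("malformed_row_rate"),
    seed = if (!is.null(seed)) seed else take("seed")
  )
}
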