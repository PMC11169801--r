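# faersmine

Signal mining for FAERS-style spontaneous adverse-event reports.

Post-marketing drug safety surveillance relies on spontaneous reporting
systems such as the FDA Adverse Event Reporting System (FAERS): quarterly
releases of `$`-delimited ASCII tables (DEMO, DRUG, REAC, THER) holding
millions of voluntarily submitted adverse-event reports. faersmine is an R
package for pharmacovigilance analysts who work with this data shape. It
covers the full analysis path:

* **Ingestion** of the FAERS ASCII dialect with per-row reject capture and a
  lossless normalized report table;
* **Deduplication** of case versions (per CASEID keep the latest FDA_DT,
  ties broken by the largest PRIMARYID);
* **Cohort construction** by drug-synonym matching restricted to
  primary-suspect (PS) role reports;
* **Descriptive tables** of sex, age band, reporter type and reporting year;
* **Disproportionality analysis** with the reporting odds ratio at MedDRA PT
  and SOC level. For the 2×2 table (a, b: cohort reports with/without the
  term; c, d: background reports with/without it):

  ROR = (a·d)/(b·c),  95% CI = exp( ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d) )

  with the standard signal criterion ROR₀₂₅ > 1 and N ≥ 2, ranking of the
  most-reported terms, exclusion lists, and labeled-vs-unexpected
  classification against drug-label term lists;
* **Time-to-onset analysis**: onset-day computation with strict date-quality
  filters, maximum-likelihood Weibull fits whose shape parameter β
  classifies the hazard as early-failure (CI < 1), random-failure (CI ∋ 1)
  or wear-out-failure (CI > 1), and Kaplan–Meier cumulative incidence;
* **Subgroup analysis** comparing signals reported by medical versus
  non-medical professionals;
* A **synthetic-data generator** producing FAERS-dialect quarters with a
  ground-truth manifest (planted RORs, Weibull onset profiles, injected
  duplicates, controlled missingness), so every stage is testable without
  downloading anything.

The methods vignette (`vignettes/faers-signal-mining.Rmd`) documents the
statistical conventions in detail.

## Worked example

A synthetic study window under the default conditions, analysed end to end:

```r
library(faersmine)

cfg <- sim_config(seed = 2024)           # 3 drugs vs 5000-report background
gen <- generate_reports(cfg)             # 6148 report versions
reports <- deduplicate(gen$reports)      # 5346 unique cases

query  <- drug_query("sirnafirst", c("sirnafirst sodium", "firstpattro",
                                     "ALN-SYN01"))
cohort <- select_ps_cohort(reports, query)   # 216 primary-suspect reports
background <- reports[!reports$caseid %in% cohort$caseid, ]

summarize_cohort(cohort)
#> <cohort_summary> total reports: 216
#>  sex:     female 37 (17.1%) / male 22 (10.2%) / missing 157 (72.7%)
#>  ...

top <- top_terms(cohort, background, k = 10)
head(classify_expectedness(top, gen$truth$drugs$sirnafirst$label_pts), 2)
#> term     level  n  ror   ci_low ci_high significant expectedness
#> loss of personal independence in daily activities
#>          PT    35  1.41  0.97   2.04    FALSE       not_significant
#> fatigue  PT    32  7.20  4.75   10.92   TRUE        unexpected
```

The planted fatigue signal (true ROR 8) is recovered with ROR 7.20
(95% CI 4.75–10.92): significant, and — being absent from the synthetic
label — classified as an unexpected signal.

```r
tto <- compute_tto(cohort)               # 51 reports with day-precision dates
tto_summary(tto)
#> median     q1     q3
#>  168.0   45.5  480.5
weibull_mle(tto)
#> <weibull_fit> n = 51
#>   shape beta = 0.825 (95% CI 0.660-1.031)
#>   scale alpha = 256.0 days
#>   profile: random_failure
km_at(km_curve(tto), c(30, 180))
#> [1] 0.216 0.510
```

The onset data were generated with shape 0.81; at 51 usable records the fit
recovers β = 0.83, with a CI still touching 1 (random failure) — exactly the
sample-size caveat the methods vignette discusses. 21.6% of onsets occur
within 30 days and 51.0% within 180 days.

```r
subgroup_signals(cohort, background)
#> <subgroup_comparison>
#>   common significant signals: 1
#>   unique to medical reporters: 8
#>   unique to non-medical reporters: 6
```

To write a synthetic quarter to disk (FAERS-dialect files plus truth
manifest), or from a shell:

```sh
Rscript inst/scripts/simulate-quarter.R --config my_config.yaml \
        --out quarter_dir --seed 42
```

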