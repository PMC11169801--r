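---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

faersmine analyses spontaneous adverse-event (AE) reports in the layout of
the FDA Adverse Event Reporting System (FAERS): quarterly `$`-delimited ASCII
tables DEMO (demographics and receipt dates), DRUG (drug names and role
codes), REAC (MedDRA Preferred Terms) and THER (therapy dates). This vignette
documents the statistical methods, the conventions adopted where the
underlying data format leaves room, and what the bundled simulator does and
does not emulate.

```{r setup}
library(faersmine)
```

## Report model and deduplication

A *case* (CASEID) can be reported repeatedly as new versions arrive; each
version has its own PRIMARYID and FDA receipt date FDA_DT. `deduplicate()`
keeps, per case, the version with the latest FDA_DT and, among receipt-date
ties, the largest PRIMARYID. Both fields are treated as orderable integers,
which is how the FAERS release prints them. The rule is deterministic
(output sorted by caseid) and idempotent, and a tie on both keys — impossible
in real data — keeps the first version seen and warns.

Dates in FAERS can be full (`YYYYMMDD`), partial (`YYYYMM`, `YYYY`), missing
or malformed. `parse_date()` is total: every string maps to one of five
precision classes and nothing ever errors, because a malformed date is
information (the report is excluded from onset analysis) rather than a fault.

Drug retrieval uses both generic and brand names, since reporters use
either. `match_drug()` matches by word-boundary containment of any
normalized synonym — verbatim FAERS names carry dose and formulation
suffixes (`"PATISIRAN SODIUM 10 MG"`), so exact equality would silently
undercount. Cohorts are restricted to reports where the target drug is the
*primary suspect* (role code PS), and cohort size counts unique cases.

Two conventions the source format does not fix, chosen here once and
configurable: the event date is taken from DEMO's EVENT_DT (THER's END_DT is
the alternative), and the therapy start date from the THER row with the
lowest drug sequence number, which is where the primary-suspect drug sits.

## Descriptive summaries

`summarize_cohort()` tabulates sex, age band, reporter type and reporting
year with an explicit missing category, so every breakdown sums to the
cohort total and percentages are computed on that total (missingness is a
finding in spontaneous data, not a nuisance). Age bands are `<18`, `18–65`,
`>65`; boundary ages 18 and 65 fall in the middle band — the closed-interval
reading of the conventional band labels, logged here because table captions
rarely say. Percentages are rounded half-up to one decimal, matching how
clinical tables are printed (base R's `round()` is half-even). Ages arrive
with unit codes and are converted to years (`DEC` ×10, `MON` ÷12, `WK`
÷52.18, `DY` ÷365.25, `HR` ÷8766); results outside [0, 150] years are set
missing with a warning.

## Disproportionality: the reporting odds ratio

For a drug–term pair, the 2×2 table counts reports in the analysis window:

|              | term present | term absent |
|--------------|:---:|:---:|
| cohort (drug primary suspect) | a | b |
| background (all other reports) | c | d |

$$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

A pair is a *significant signal* when the lower CI bound exceeds 1 and the
report count N = a is at least 2. The counting unit is the unique
(report, term) pair: a PT listed twice on a report counts once, and at SOC
level a report contributes once per SOC however many of its PTs map there.

Numerical and design choices:

* **Zero cells** make the estimate *incalculable* rather than applying the
  Haldane–Anscombe 0.5 correction: the signal criterion already requires
  N ≥ 2, so a continuity-corrected estimate would never change a decision,
  and uncorrected output is easier to audit.
* **Background**: by default the comparator excludes the cohort itself
  ("all other reports"); including it is a flag away, and at the usual
  cohort-to-background ratios the difference is negligible.
* **Ranking**: `top_terms()` ranks by N descending with alphabetical
  tie-break, so the "top 50" list is reproducible run to run.
* **Exclusion lists** (outcome terms, injection/infusion terms, terms that
  are symptoms of the treated disease itself) are plain text files, one term
  per line with `#` comments, because these sets are study-specific
  editorial decisions, not algorithm constants.
* **Expectedness**: significant terms found on the drug's label term list
  are `labeled`; significant terms absent from it are `unexpected` signals;
  `cross_drug_overlap()` intersects these sets across drugs.
* **No multiplicity correction** is applied to the per-term CIs. This is
  the field's standard practice for hypothesis-generating signal detection,
  and a known limitation: among 50 ranked terms some lower bounds exceed 1
  by chance.
* PT→SOC mapping comes from a user-supplied two-column table
  (`read_meddra_map()`); MedDRA is licensed and is not shipped. Unmapped
  PTs route to an `UNMAPPED` sentinel rather than dropping reports.

## Time to onset and the Weibull shape parameter

The onset interval is event date minus therapy start in calendar days.
`compute_tto()` keeps a report only when both dates have day precision and
the event does not precede the start; exclusion counts are attached by
reason. One record is emitted per report. Summaries use median and
quartiles with linear interpolation (`quantile()` type 7), so half-day
quartiles can occur.

`weibull_mle()` fits the two-parameter Weibull by maximum likelihood and
reads the hazard off the shape parameter β:

* 95% CI of β entirely below 1 → **early failure** (risk decreasing over time),
* CI containing 1 → **random failure** (roughly constant risk),
* CI entirely above 1 → **wear-out failure** (risk increasing).

Implementation notes:

* Optimization runs on (log β, log α) — the natural unconstrained scale —
  with analytic gradients, BFGS, and a Newton polish on the score until the
  maximum score component is below 1e-8 per observation; non-convergence
  errors out with the per-iteration score trace rather than returning a
  doubtful fit.
* The CI for β is the Wald interval on log β from the observed information
  matrix, symmetric in log space. Profile-likelihood intervals would differ
  slightly in small samples; the method is stated so users can compare.
* **Zero-day onsets** lie outside the Weibull support. They are shifted to
  0.5 day (configurable) instead of being discarded: same-day onset is real
  and common, and dropping it would bias β upward.
* Fits require n ≥ 10 by default; all-identical samples are rejected as
  degenerate.
* At small n the shape MLE is biased upward by a few percent (visible at
  n ≈ 70, negligible by n ≈ 450); the package reports the plain MLE and
  leaves bias correction to the user, as the field's tooling does.

`km_curve()` wraps the Kaplan–Meier estimator (via the survival package)
and returns cumulative incidence. Spontaneous reports are events by
construction, so there is no censoring and the KM curve equals the
empirical CDF exactly; the KM machinery is kept so the API generalises to
censored follow-up data.

## Subgroup analysis by reporter type

Reporter occupation codes map to medical (`MD`, `PH`, `OT`, `HP`) versus
non-medical (`CN`, `LW`) professionals; unknown reporters are excluded from
both strata. `subgroup_signals()` reruns the ranking and ROR machinery
within each stratum and reports common and stratum-unique significant
signals. The comparator is restricted to the same reporter class by default
so each stratum's ROR compares like with like — reporting cultures differ
systematically between professionals and consumers — but an unrestricted
background is available via `stratify_background = FALSE`.

## The synthetic-data generator

`generate_quarter()` writes DEMO/DRUG/REAC/THER files (plus a JSON truth
manifest) that re-ingest through `read_quarter()` byte-faithfully, so the
whole pipeline is testable end to end with known ground truth.

What it emulates, with the default `sim_config()` representing the package's
reference study conditions:

* three target drugs with primary-suspect cohorts of 216, 26 and 104
  reports against a 5,000-report background — a tenfold scale-down of a
  real multi-year reporting window for a rare-disease drug class;
* planted drug–event associations: each signal PT is reported with
  probability `p = ROR·q/(1 − q + ROR·q)` in the cohort against base
  probability `q` (`tune_signal_probability()`), which makes the expected
  report-level odds ratio exactly the target; signal PTs are excluded from
  the filler-term pool so the planted odds are not diluted;
* Weibull onset intervals with shapes 0.81 / 1.48 / 0.81 and scales fixed
  from target medians via `α = median/(ln 2)^{1/β}` (325.5, 131.9 and 380.5
  days);
* duplicate case versions at rate 0.15 (the approximate duplication level
  of public spontaneous-report databases), always strictly newer than the
  original so the dedup rule has a unique right answer, with a fraction
  tying on FDA_DT to exercise the PRIMARYID tie-break;
* missingness of sex (0.716), age (0.886) and occupation, a 59/40/1
  medical/non-medical/unknown reporter mix, and a date-precision mix
  (50% day, 20% month, 10% year, 15% missing, 5% invalid) so that onset
  analysis sees realistic attrition;
* a bundled synthetic vocabulary of ~170 PTs with an invented SOC
  assignment and Zipf-like base frequencies (MedDRA itself is licensed and
  deliberately absent).

What it does not emulate: real MedDRA term frequencies or co-reporting
structure, drug co-medication patterns, reporting-volume trends over time,
country effects, and narrative-level duplicates that differ in content.
Passing recovery tests on this generator therefore demonstrates that the
pipeline's arithmetic and filters are correct under controlled conditions —
not that any particular real-world signal is valid.

All randomness flows from the single `seed` field through R's generator in
a fixed drawing order, so runs are fully reproducible; a fixed seed yields
byte-identical output files.

```{r, eval = FALSE}
cfg <- sim_config(seed = 2024)
paths <- generate_quarter(cfg, "synthetic_quarter")

rq <- read_quarter(paths$paths[["demo"]], paths$paths[["drug"]],
                   paths$paths[["reac"]], paths$paths[["ther"]])
reports <- deduplicate(build_reports(rq))
cohort <- select_ps_cohort(reports, drug_query("sirnafirst",
                                               c("firstpattro", "ALN-SYN01",
                                                 "sirnafirst sodium")))
background <- reports[!reports$caseid %in% cohort$caseid, ]

summarize_cohort(cohort)
top_terms(cohort, background, k = 50)
weibull_mle(compute_tto(cohort))
subgroup_signals(cohort, background)
```

## Verification strategy and problem sizes

The test suite verifies each stage against independent oracles: the ROR and
its CI against separately structured odds arithmetic over an exhaustive
grid of small tables; the Weibull MLE against a second, independent fitting
routine and against simulation truth (200 replicates at n = 447 recover a
shape of 0.81 to within ±0.05 on the mean; 200 replicates at n = 73 recover
1.48 to within ±0.15, the wider band reflecting small-sample MLE bias);
KM output against the empirical CDF; planted RORs of 8 are covered by the
estimated 95% CI in well over 90% of 200 simulated quarters of 860 reports;
and exponential samples (shape 1) classify as random failure in over 85% of
replicates at n = 500. These sizes keep the full suite to a couple of
minutes while leaving the statistical assertions comfortably away from
their thresholds.

## Known limitations

* Disproportionality measures reporting association, not causation or
  incidence; the background is other spontaneous reports, not an exposed
  population.
* No multiple-testing adjustment (see above).
* Month- and year-precision dates are excluded from onset analysis rather
  than interval-censored; an interval-censored Weibull would use more data
  at the cost of a heavier model.
* Probabilistic record linkage beyond the CASEID/FDA_DT/PRIMARYID rule
  (e.g. detecting duplicates across manufacturers) is out of scope.
* One onset record per report: a report listing several AEs contributes its
  single event date, not one interval per PT.
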