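# faersdp

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event reports, built for the question of
depression and suicide/self-injury risk under GLP-1 receptor agonist
(GLP-1RA) plus metformin combination therapy versus GLP-1RA monotherapy —
and reusable for any active-comparator disproportionality study on data in
the FAERS quarterly ASCII layout.

Spontaneous-reporting databases have no denominator, so `faersdp` asks the
disproportionality question instead: is the event reported more often than
expected under the target exposure, relative to an active comparator? On
the 2x2 table with cells *a* (target exposure, target event), *b* (target,
other events), *c* (comparator, event), *d* (comparator, other):

- **Reporting odds ratio** ROR = *ad*/(*bc*), with
  95% CI = exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d));
- **Information component** IC = log2 of the observed-to-expected reporting
  ratio, E = (a+b)(a+c)/N, with a shrinkage (gamma-posterior) IC025 lower
  bound by default;
- **Signal criteria**: a ≥ 3 cases, ROR CI lower limit > 1, and IC025 > 0,
  jointly;
- **Weibull shape parameter (WSP) test** on time-to-onset: shape β and its
  95% CI classify the hazard as early-failure (CI < 1), random (CI spans
  1), or wear-out (CI > 1).

The package covers the full pipeline: '$'-delimited DEMO/DRUG/REAC/THER/
OUTC/RPSR ingestion, keep-latest case deduplication, drug-name
normalization (brands, salts, development codes such as `LY3298176`),
SMQ preferred-term event classification (the 12-PT depression-excluding-
suicide and 9-PT suicide/self-injury narrow lists ship as editable CSV),
exposure cohorting by FAERS role codes, descriptive cohort tables with a
pinned chi-squared/Fisher test-selection rule, unmasking reruns excluding
psychotropic or antidiabetic co-medication, sex-stratified subgroup RORs,
and Weibull TTO fits with failure-type classification. A synthetic
FAERS-like generator with known ground truth (injected odds ratios,
duplicate contamination, Weibull onset times) makes every stage testable
without the FAERS download.

## Worked example

Simulate 20,000 reports with a 10-fold injected reporting-rate multiplier
for suicide/self-injury under combination exposure, contaminate with 5%
duplicates, then run the analysis stages:

```r
library(faersdp)

cfg <- sim_config(
  n_reports = 20000,
  signal_injections = list(list(exposure = "combination",
                                term_set = "suicide_self_injury",
                                multiplier = 10)),
  seed = 42)
g   <- generate_dataset(cfg)
d   <- inject_duplicates(g$tables, 0.05, seed = 43, ground_truth = g$ground_truth)
tabs <- normalize_drugs(deduplicate(d$tables))
fr   <- report_frame(tabs)

table(fr$exposure)
#>    combination    glp1ra_only metformin_only          other
#>            997          15037           2018           1948

signal_estimate(build_contingency(fr, "suicide_self_injury"))
#> <signal_estimate> a=107 b=890 c=165 d=14872
#>   ROR 10.84 (95% CI 8.42-13.95)  IC 2.63 (IC025 2.34, shrinkage)
#>   signal: TRUE

theoretical_or(cfg, "suicide_self_injury")   # the configured estimand
#> [1] 11.181
```

The empirical ROR of 10.84 (CI 8.42–13.95) recovers the theoretical odds
ratio of 11.18 implied by the injected rates, and the joint signal
criteria fire. Time-to-onset in the monotherapy cohort:

```r
tto  <- extract_tto(tabs, "glp1ra")
keep <- fr$event_suicide_self_injury & fr$exposure == "glp1ra_only" & tto$included
fit_weibull(tto$tto_days[keep])
#> <weibull_fit> n=99  median 37.0 (IQR 13.0-129.0)
#>   scale 77.22 (57.22-104.21)  shape 0.69 (0.60-0.81)  early
```

The fitted shape of 0.69 with CI below 1 classifies the hazard as
early-failure: onsets concentrate early in treatment — which is exactly the
generating distribution (shape 0.69, scale 79.63) the simulation drew from.

The full orchestration — ingest or simulate, dedup, cohorts, descriptive
tables, baseline/unmasked/sex-stratified signals, TTO, reporting-year
counts, run manifest — is one call, `run_pipeline()`, driven by a YAML
config (see `?run_config`), with a thin command-line wrapper in
`inst/cli/faersdp` offering `simulate`, `ingest`, `signal`, `describe`,
`tto` and `run-all` subcommands.

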