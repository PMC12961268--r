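---
title: "Methods: disproportionality and time-to-onset analysis of FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdp)
```

## The problem

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System (FAERS) collect unsolicited reports of suspected adverse drug
reactions. They have no denominator — nobody knows how many patients took a
drug without reporting anything — so risk cannot be estimated directly.
Disproportionality analysis works around this by asking whether a given
event is reported *more often than expected* for one exposure relative to a
comparator, on a 2x2 table of exposure by event among the reports
themselves.

`faersdp` implements an **active-comparator** version of this design for
the question of depression and suicide/self-injury risk under combination
therapy with GLP-1 receptor agonists (GLP-1RAs) plus metformin versus
GLP-1RA monotherapy. The comparator is not the whole database but the
monotherapy cohort: cases and non-cases are counted *within* the two
exposure cohorts, which removes much of the confounding-by-indication that
a database-wide background would carry. A database-wide comparator remains
available through configuration.

## From raw tables to cohorts

FAERS distributes quarterly `'$'`-delimited ASCII tables (DEMO, DRUG, REAC,
THER, OUTC, RPSR) keyed by a report ID (`primaryid`) and a case ID
(`caseid`). The pipeline:

1. **Ingestion** (`read_quarter()`): strict field-count validation against
   the header; dates kept as 4/6/8-digit strings and parsed to calendar
   dates only when complete. The dialect has no quoting, so embedded `'$'`
   is rejected at write time rather than silently corrupted.
2. **Deduplication** (`deduplicate()`): FAERS cases are resubmitted as
   follow-ups under the same `caseid`. We keep, per case, the report with
   the latest receipt date, ties broken by the largest `primaryid` — the
   standard practice for FAERS analyses. The operation is idempotent and
   never increases the report count.
3. **Drug-name normalization** (`normalize_drug_name()`): verbatim strings
   (brands, salts, development codes such as `LY3298176`) are folded
   case- and whitespace-insensitively onto canonical ingredients using a
   shipped synonym table covering the eight GLP-1RAs and metformin; user
   tables merge over the defaults. Unknown names pass through unchanged
   with a `matched = FALSE` flag, so normalization is total.
4. **Exposure cohorting** (`classify_exposure()`): a report is
   `combination` if a GLP-1RA appears in a *target role* (primary suspect,
   PS, by default) and metformin appears in any role; `glp1ra_only` if a
   GLP-1RA is in a target role and metformin is absent entirely;
   `metformin_only` symmetrically; `other` otherwise. The PS default
   reflects the convention that the primary-suspect drug is the one the
   reporter deemed most likely causal; the partner's role set is
   configurable because combination partners are recorded under varying
   roles.
5. **Event classification** (`classify_event()`): two narrow standardised
   MedDRA query (SMQ) preferred-term lists are shipped — depression
   excluding suicide/self-injury (12 PTs) and suicide/self-injury (9 PTs).
   Matching is case-insensitive exact PT matching; broad-scope SMQ terms
   and the full MedDRA hierarchy are out of scope.

## Signal statistics

For cells `a` (target exposure, target event), `b` (target, other events),
`c` (comparator, event), `d` (comparator, other), with `N = a+b+c+d`:

* **Reporting odds ratio**: `ROR = ad/(bc)` with
  `95% CI = exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`. No
  continuity correction is applied; a zero cell makes the estimate
  non-estimable rather than silently shifted, since the signal criteria
  require at least three cases anyway.
* **Information component**: the log2 observed-to-expected reporting ratio
  with expected count `E = (a+b)(a+c)/N`. Two estimators are provided:
  * `shrinkage` (default): `IC = log2((a+0.5)/(E+0.5))` and `IC025` as the
    log2 of the 2.5% quantile of the Gamma(a+0.5, E+0.5) posterior. This
    is the standard credibility-interval formulation in modern Bayesian
    pharmacovigilance monitoring; the +0.5 shrinkage pulls small-count
    signals toward zero and controls false positives.
  * `plain`: `IC = log2(aN/((a+c)(a+b)))` with `IC025 = IC − 2·SD`,
    `SD = (1/ln 2)·sqrt(1/a)`. The `IC − 2·SD` form is common in applied
    reports but leaves the SD estimator unstated; ours is a delta-method
    approximation to the posterior spread and is labelled as such. It is
    selectable for comparability, not the default.
* **Signal criteria** (`evaluate_signal()`): a signal requires jointly
  `a ≥ 3`, ROR 95% CI lower limit `> 1`, and `IC025 > 0`. The conjunction
  is monotone in `a` at fixed `b`, `c`, `d`.

**Unmasking** (`run_unmasking()`) re-estimates a signal after removing, from
both cohorts, every report containing (in any role) a drug from classes
that could themselves cause or mask the event: psychotropic classes
(benzodiazepines, antidepressants, antipsychotics, opioids, sedatives,
GABAergic drugs) or other antidiabetic classes (SGLT-2, DPP-4 inhibitors,
thiazolidinediones, alpha-glucosidase inhibitors, sulfonylureas). The class
membership lists ship as editable CSV.

**Sex subgroups** (`sex_subgroup_analysis()`) compute per-PT estimates
separately in female and male strata, with reports of unknown sex excluded
from both so the strata stay disjoint and interpretable, and report the
male/female ROR ratio (undefined when either stratum is non-estimable).

## Descriptive comparisons and test selection

`build_descriptive_table()` tabulates sex, weight band (<50 / 50–100 /
>100 kg / Unknown), age band (<18 / 18–64 / >64 / Unknown), report source,
and serious outcome for the event-positive reports of both cohorts.
Percentages use the full cohort size as denominator, Unknown rows included,
so each characteristic block sums to 100%. Each report carries a single
worst serious outcome (priority DE > LT > HO > DS > CA > RI > OT, else
Missing), which keeps outcome rows summing to the cohort size.

Outcome rows are compared between cohorts by the pinned rule: **Pearson
chi-squared without continuity correction when all four expected counts are
at least 5, otherwise the two-sided Fisher exact test** with the
probability-mass convention (two-sided p is the sum of all table
probabilities not exceeding the observed table's — the convention of
`stats::fisher.test()`). This specific rule is pinned because it reproduces
the printed reference p-values for both regimes (a Yates-corrected or
Fisher-always rule does not); the Fisher branch is verified in the test
suite against full hypergeometric enumeration on every 2x2 table with
total at most 30. Two printed Disability-row p-values are not reproduced by
any variant of this rule and are deliberately not asserted.

## Time-to-onset analysis

TTO is the day count from the earliest *fully dated* therapy start of a
target-class drug to the event date. Partial dates (year or year+month) are
excluded rather than imputed — fabricating a day component would bias short
onsets — as are non-positive intervals, each with a recorded exclusion
reason. Medians and quartiles use linear interpolation between order
statistics.

`fit_weibull()` fits the two-parameter Weibull by maximum likelihood:
profile likelihood in the shape (a one-dimensional root-find of the score
equation, tolerance 1e-10) with the scale in closed form given the shape.
This is robust and fast; censoring is out of scope because spontaneous
reports record realised onsets only. 95% CIs are Wald intervals on the log
parameters from the observed information matrix, exponentiated so bounds
stay positive. Degenerate samples (n < 3 or all values identical) error
rather than returning meaningless estimates.

The **Weibull shape parameter (WSP) test** reads the hazard over time off
the shape CI: `early` failure (decreasing hazard) when the CI lies entirely
below 1, `wear_out` (increasing) when entirely above 1, and `random`
(roughly constant) whenever the CI contains 1 — the residual category, so
the three regions partition all valid CIs. Onset histograms use bins
1–30 / 31–90 / 91–180 / >180 days, approximating "first month / 1–3 / 3–6 /
beyond 6 months" with 30-day blocks.

A rank-based (Wilcoxon) comparison of TTO distributions is provided
(`compare_tto()`); reference median comparisons in the field name no test,
so its p-values are reported but not asserted against any external value.

## The synthetic generator

`generate_dataset()` draws FAERS-like bundles with known ground truth so
every downstream stage is testable without the (non-redistributable) FAERS
download. Defaults define the emulated study conditions and were fixed
once, from the published cohort structure where available:

* exposure mix 5% combination / 75% GLP-1RA monotherapy / 10% metformin /
  10% other — a roughly 1:15 combination-to-monotherapy ratio matching the
  published cohort totals (2,634 vs 40,841);
* monotherapy background event probabilities 0.0135 (depression set) and
  0.0116 (suicide/self-injury set), the rates implied by the published
  event counts over the monotherapy cohort;
* Weibull onset-time parameters per exposure taken from the published WSP
  table (e.g. scale 79.63, shape 0.69 for GLP-1RA monotherapy
  suicide/self-injury); event date = therapy start + onset rounded to whole
  days, minimum 1;
* demographic and serious-outcome category probabilities near the printed
  cohort characteristics, with explicit Unknown categories since the
  reference tables report Unknown rows;
* duplicate rate 0.05 (duplicates are near-copies with the same `caseid`,
  a new `primaryid` and a later receipt date, so they exercise the
  keep-latest rule); partial-date rate 0.2 (dates degraded to year+month,
  half of those to year); concomitant-drug probability 0.15, which gives
  the unmasking stage something to exclude.

Signal injection multiplies a term set's reporting rate for one exposure
pattern; `theoretical_or()` returns the odds ratio the configured rates
imply, which is the estimand the downstream ROR recovers. Identical
configurations (including the seed) produce byte-identical output.

What the generator does **not** emulate: realistic drug-market shares, the
full MedDRA hierarchy, correlated reporting (stimulated reporting waves,
country effects), indication-based selection ("diabetic or obese"
filtering; an indication hook exists but no filter semantics are asserted),
and free-text drug-name noise beyond the shipped synonym variants. Passing
tests therefore demonstrate that the statistical machinery recovers known
truth under a clean FAERS-like structure — not that any particular
real-world signal is causal, nor that real FAERS quirks (reporting bias,
missing denominators, duplicate submissions evading `caseid` linkage) are
overcome.

## Validation problem sizes

The test suite exercises: deduplication and round-trip I/O on small
hand-built bundles; the Fisher branch against hypergeometric enumeration on
all 2x2 tables with total ≤ 30; Weibull shape recovery and CI coverage over
200 replicates of n = 111 at shapes 0.5–1.2 (mean shape within 5%, coverage
within 95% ± 4 points); odds-ratio recovery of an injected multiplier 10 at
50,000 reports; null calibration (no injection) over 100 replicates of
8,000 reports with a signal-flag rate required below 10%; and power over
100 replicates of 50,000 reports at injected odds ratio 10, required above
90%. These sizes make the whole suite run in a few minutes on one core
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Published database-wide RORs are not reproducible from printed cohort
  totals alone (the reconstruction from the printed margins gives ≈3.49
  under the active-comparator design); the package asserts only quantities
  recomputable from printed counts or recoverable from simulation truth.
* The `plain` IC's SD is an approximation by construction; use the default
  shrinkage method for decision-making.
* No censoring in the Weibull fit: reports without a realised event simply
  never enter the TTO sample, which is the field's convention but means
  the fitted distribution describes reported onsets, not time-to-event in
  a cohort sense.
* Deduplication can only merge what shares a `caseid`; true duplicates
  submitted under different case IDs pass through.
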