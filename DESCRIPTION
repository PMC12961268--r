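Package: faersdp
Title: Disproportionality and Time-to-Onset Analysis for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style quarterly ASCII report tables: ingestion of '$'-delimited
    DEMO/DRUG/REAC/THER/OUTC/RPSR files, drug-name normalization against a
    synonym table, case deduplication, exposure cohorting (combination
    therapy versus monotherapy with an active comparator), standardised
    MedDRA query (SMQ) event classification, reporting odds ratio (ROR)
    and Bayesian information component (IC) signal statistics with
    configurable criteria, unmasking reruns, sex-stratified subgroup
    estimates, descriptive cohort tables with chi-squared/Fisher test
    selection, and Weibull time-to-onset analysis with failure-type
    classification. Includes a synthetic FAERS-like data generator with
    known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
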