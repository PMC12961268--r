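# Small hand-built FAERS bundle: four reports, one duplicated case.
#  C0000001: semaglutide PS + metformin C, suicidal ideation, full dates, F, DE
#            (two versions; the 2023-03-01 receipt must win dedup)
#  C0000002: semaglutide PS only, depressed mood, partial event date, M
#  C0000003: insulin PS + metformin C (no GLP-1RA in target role), nausea
#  C0000004: metformin PS alone, depression, F
mini_bundle <- function() {
  demo <- data.frame(
    primaryid = c("11", "12", "21", "31", "41"),
    caseid = c("C0000001", "C0000001", "C0000002", "C0000003", "C0000004"),
    fda_dt = c("20230101", "20230301", "20230110", "20230215", "20230320"),
    event_dt = c("20230131", "20230131", "202303", "20230210", "20230301"),
    sex = c("F", "F", "M", "", "F"),
    age = c("54", "54", "70", "", "45"),
    age_cod = c("YR", "YR", "YR", "", "YR"),
    wt = c("88", "88", "", "120", ""),
    wt_cod = c("KG", "KG", "", "KG", ""),
    occp_cod = c("MD", "MD", "CN", "CN", "HP"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("11", "11", "12", "12", "21", "31", "31", "41"),
    caseid = demo$caseid[c(1, 1, 2, 2, 3, 4, 4, 5)],
    drug_seq = c("1", "2", "1", "2", "1", "1", "2", "1"),
    role_cod = c("PS", "C", "PS", "C", "PS", "PS", "C", "PS"),
    drugname = c("OZEMPIC", "METFORMIN HCL", "OZEMPIC", "METFORMIN HCL",
                 "  semaglutide ", "INSULIN GLARGINE", "GLUCOPHAGE",
                 "METFORMIN"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("11", "11", "12", "12", "21", "31", "41"),
    caseid = demo$caseid[c(1, 1, 2, 2, 3, 4, 5)],
    pt = c("Suicidal ideation", "Nausea", "Suicidal ideation", "Nausea",
           "Depressed mood", "Nausea", "Depression"),
    stringsAsFactors = FALSE)
  ther <- data.frame(
    primaryid = c("11", "12", "21", "31", "41"),
    caseid = demo$caseid[c(1, 2, 3, 4, 5)],
    dsg_drug_seq = c("1", "1", "1", "1", "1"),
    start_dt = c("20230101", "20230101", "202301", "20230101", "20230210"),
    stringsAsFactors = FALSE)
  outc <- data.frame(
    primaryid = c("11", "12", "41"),
    caseid = demo$caseid[c(1, 2, 5)],
    outc_cod = c("DE", "DE", "HO"),
    stringsAsFactors = FALSE)
  rpsr <- data.frame(
    primaryid = c("11", "12", "21", "31", "41"),
    caseid = demo$caseid[c(1, 2, 3, 4, 5)],
    rpsr_cod = c("EXP", "EXP", "PER", "EXP", "PER"),
    stringsAsFactors = FALSE)
  faers_tables(demo, drug, reac, ther, outc, rpsr, quarter = "2023Q1")
}

# report_frame-shaped fixture with the printed characteristics of one study
# cohort pair: sex and serious-outcome counts per cohort for one event.
cohort_fixture_frame <- function(event, target_counts, comparator_counts) {
  build <- function(counts, exposure) {
    sex <- rep(c("F", "M", "Unknown"), counts$sex)
    outcome <- rep(c("DE", "DS", "HO", "LT", "OT", "Missing"), counts$outcome)
    n <- length(sex)
    stopifnot(length(outcome) == n)
    df <- data.frame(
      primaryid = paste0(exposure, seq_len(n)),
      caseid = paste0(exposure, seq_len(n)),
      exposure = exposure, sex = sex,
      age_years = NA_real_, wt_kg = NA_real_, source = "CN",
      outcome = outcome, year = 2020L, stringsAsFactors = FALSE)
    df
  }
  frame <- rbind(build(target_counts, "combination"),
                 build(comparator_counts, "glp1ra_only"))
  frame[[paste0("event_", event)]] <- TRUE
  frame
}

# Published cohort margins (suicide/self-injury and depression studies)
published_suicide_cohorts <- function() {
  cohort_fixture_frame("suicide_self_injury",
               list(sex = c(37, 62, 5), outcome = c(40, 3, 14, 11, 29, 7)),
               list(sex = c(267, 179, 29), outcome = c(59, 23, 34, 72, 211, 76)))
}

published_depression_cohorts <- function() {
  cohort_fixture_frame("depression_ex_suicide",
               list(sex = c(31, 16, 0), outcome = c(1, 5, 5, 3, 20, 13)),
               list(sex = c(370, 140, 40), outcome = c(9, 34, 37, 45, 163, 262)))
}

# brute-force two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b
  k <- a + c
  n <- a + b + c + d
  xs <- max(0, k - (c + d)):min(m1, k)
  probs <- dhyper(xs, m1, n - m1, k)
  p_obs <- dhyper(a, m1, n - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

getrow <- function(df, characteristic, level) {
  df[df$characteristic == characteristic & df$level == level, , drop = FALSE]
}
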