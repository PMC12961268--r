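#' Configuration for the synthetic FAERS-like generator
#'
#' Defines the data-generating conditions for a simulated spontaneous-report
#' dataset: exposure mix, background reporting rates of the two study term
#' sets, injected disproportionality, Weibull time-to-onset distributions,
#' demographics, serious-outcome rates, duplicate contamination and partial
#' dates. Defaults emulate the cohort structure of the GLP-1RA / metformin
#' study: a roughly 1:15 combination-to-monotherapy mix and monotherapy
#' background event rates near those implied by the published cohort sizes.
#'
#' @param n_reports number of (pre-duplication) reports.
#' @param exposure_mix named probabilities over
#'   `combination`, `glp1ra_only`, `metformin_only`, `other`; must sum to 1.
#' @param background_event_rate named per-report probability of each term
#'   set's event under multiplier 1.
#' @param signal_injections list of lists with fields `exposure`,
#'   `term_set`, `multiplier` (> 0); reporting rate for that cell becomes
#'   `min(1, rate * multiplier)`.
#' @param tto_distributions named list (one per exposure pattern) of
#'   `c(scale, shape)` Weibull parameters in days; both strictly positive.
#' @param sex_probs,age_probs,weight_probs,source_probs named probability
#'   vectors (each summing to 1) with explicit `Unknown` categories.
#' @param outcome_rates list with probability vectors `event` and
#'   `background` over the single worst serious outcome
#'   `DE`, `DS`, `HO`, `LT`, `OT`, `Missing`.
#' @param duplicate_rate fraction in `[0, 1)` of reports to duplicate.
#' @param partial_date_rate fraction in `[0, 1)` of event/start dates
#'   degraded to year+month (half of those further to year only).
#' @param concomitant_rate probability a report carries one extra
#'   concomitant-class drug (psychotropic/antidiabetic/other), which gives
#'   the unmasking analyses something to exclude.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(
    n_reports = 10000L,
    exposure_mix = c(combination = 0.05, glp1ra_only = 0.75,
                     metformin_only = 0.10, other = 0.10),
    background_event_rate = c(depression_ex_suicide = 0.0135,
                              suicide_self_injury = 0.0116),
    signal_injections = list(),
    tto_distributions = list(
      combination = c(scale = 70.21, shape = 0.81),
      glp1ra_only = c(scale = 79.63, shape = 0.69),
      metformin_only = c(scale = 92.40, shape = 0.47),
      other = c(scale = 60, shape = 1)),
    sex_probs = c(F = 0.56, M = 0.38, Unknown = 0.06),
    age_probs = c(`18-64` = 0.55, `>64` = 0.15, Unknown = 0.30),
    weight_probs = c(`<50 kg` = 0.005, `50-100 kg` = 0.27, `>100 kg` = 0.14,
                     Unknown = 0.585),
    source_probs = c(CN = 0.53, HP = 0.12, MD = 0.28, PH = 0.04, OT = 0.015,
                     Unknown = 0.015),
    outcome_rates = list(
      event = c(DE = 0.124, DS = 0.049, HO = 0.072, LT = 0.152, OT = 0.444,
                Missing = 0.159),
      background = c(DE = 0.01, DS = 0.02, HO = 0.08, LT = 0.02, OT = 0.35,
                     Missing = 0.52)),
    duplicate_rate = 0.05,
    partial_date_rate = 0.2,
    concomitant_rate = 0.15,
    seed = 1L) {
  check_probs <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("configuration error: probability vector `", field,
           "` must be non-negative and sum to 1", call. = FALSE)
    }
  }
  check_probs(exposure_mix, "exposure_mix")
  check_probs(sex_probs, "sex_probs")
  check_probs(age_probs, "age_probs")
  check_probs(weight_probs, "weight_probs")
  check_probs(source_probs, "source_probs")
  check_probs(outcome_rates$event, "outcome_rates$event")
  check_probs(outcome_rates$background, "outcome_rates$background")
  if (any(background_event_rate < 0) || any(background_event_rate > 1)) {
    stop("configuration error: `background_event_rate` must be in [0, 1]",
         call. = FALSE)
  }
  for (inj in signal_injections) {
    if (!all(c("exposure", "term_set", "multiplier") %in% names(inj))) {
      stop("configuration error: each `signal_injections` entry needs ",
           "exposure, term_set, multiplier", call. = FALSE)
    }
    if (inj$multiplier <= 0) {
      stop("configuration error: `signal_injections` multiplier must be > 0",
           call. = FALSE)
    }
  }
  for (nm in names(tto_distributions)) {
    p <- tto_distributions[[nm]]
    if (any(p[c("scale", "shape")] <= 0)) {
      stop("configuration error: `tto_distributions$", nm,
           "` must have strictly positive scale and shape", call. = FALSE)
    }
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("configuration error: `duplicate_rate` must be in [0, 1)",
         call. = FALSE)
  }
  if (partial_date_rate < 0 || partial_date_rate >= 1) {
    stop("configuration error: `partial_date_rate` must be in [0, 1)",
         call. = FALSE)
  }
  stopifnot(n_reports >= 1)
  structure(list(
    n_reports = as.integer(n_reports), exposure_mix = exposure_mix,
    background_event_rate = background_event_rate,
    signal_injections = signal_injections,
    tto_distributions = tto_distributions, sex_probs = sex_probs,
    age_probs = age_probs, weight_probs = weight_probs,
    source_probs = source_probs, outcome_rates = outcome_rates,
    duplicate_rate = duplicate_rate, partial_date_rate = partial_date_rate,
    concomitant_rate = concomitant_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# per-(exposure, term_set) reporting rate after injection
injected_rates <- function(config) {
  exposures <- names(config$exposure_mix)
  sets <- names(config$background_event_rate)
  grid <- expand.grid(exposure = exposures, term_set = sets,
                      stringsAsFactors = FALSE)
  grid$multiplier <- 1
  for (inj in config$signal_injections) {
    hit <- grid$exposure == inj$exposure & grid$term_set == inj$term_set
    grid$multiplier[hit] <- inj$multiplier
  }
  grid$rate <- pmin(1, config$background_event_rate[grid$term_set] *
                      grid$multiplier)
  grid
}

background_pts <- c("nausea", "headache", "diarrhoea", "vomiting",
                    "dizziness", "fatigue", "rash")

sim_drug_pool <- function() {
  dc <- drug_classes()
  list(glp1ra = dc$drug[dc$class == "glp1ra"],
       metformin = "metformin",
       concomitant = dc$drug[!dc$class %in% c("glp1ra", "metformin")],
       other = c("aspirin", "ibuprofen", "atorvastatin", "lisinopril",
                 "omeprazole", "levothyroxine"))
}

# a verbatim spelling for each canonical name, to exercise normalization
verbatim_spelling <- function(canonical, syn) {
  map <- unclass(syn)
  vapply(canonical, function(drug) {
    alts <- names(map)[map == drug]
    if (length(alts)) sample(alts, 1L) else toupper(drug)
  }, "", USE.NAMES = FALSE)
}

degrade_dates <- function(dates_yyyymmdd, rate) {
  n <- length(dates_yyyymmdd)
  u <- stats::runif(n)
  out <- dates_yyyymmdd
  part <- u < rate
  to_month <- part & u >= rate / 2
  to_year <- part & u < rate / 2
  out[to_month] <- substr(out[to_month], 1, 6)
  out[to_year] <- substr(out[to_year], 1, 4)
  out
}

#' Generate a synthetic FAERS-like dataset with known ground truth
#'
#' Draws `n_reports` reports under a [sim_config()]: exposure pattern, SMQ
#' events (background rate times any injected multiplier), reactions, drugs
#' with FAERS role codes (every report has a primary-suspect drug),
#' demographics, serious outcomes, and dates in which the event follows the
#' therapy start by a Weibull-distributed onset time (rounded to whole days,
#' minimum 1). Identical configurations (including the seed) produce
#' identical output.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (a [faers_tables] bundle) and `ground_truth`
#'   (class `sim_ground_truth`): the per-(exposure, term-set) theoretical
#'   rates and expected 2x2 cells at `n_reports`, the per-report true
#'   exposure/event/TTO assignments, and the (initially empty) duplicate
#'   case-ID list.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  exposures <- names(config$exposure_mix)
  sets <- names(config$background_event_rate)
  rates <- injected_rates(config)

  caseid <- sprintf("%08d", seq_len(n) + 10000000L)
  primaryid <- paste0(caseid, "1")
  exposure <- sample(exposures, n, replace = TRUE, prob = config$exposure_mix)

  # events per term set
  event <- matrix(FALSE, n, length(sets), dimnames = list(NULL, sets))
  for (s in sets) {
    r <- rates$rate[match(paste(exposure, s), paste(rates$exposure, rates$term_set))]
    event[, s] <- stats::runif(n) < r
  }
  any_event <- rowSums(event) > 0L

  # dates: start -> event (Weibull TTO) -> receipt
  start_date <- as.Date("2014-01-01") +
    floor(stats::runif(n, 0, as.integer(as.Date("2023-08-31") - as.Date("2014-01-01")) + 1))
  tto_true <- integer(n)
  for (ex in exposures) {
    idx <- which(exposure == ex)
    p <- config$tto_distributions[[ex]]
    if (is.null(p)) p <- c(scale = 60, shape = 1)
    tto_true[idx] <- pmax(1L, as.integer(round(
      stats::rweibull(length(idx), shape = p[["shape"]], scale = p[["scale"]]))))
  }
  event_date <- start_date + tto_true
  fda_date <- event_date + stats::rpois(n, 20)

  # demographics
  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  sex[sex == "Unknown"] <- ""
  age_band <- sample(names(config$age_probs), n, TRUE, config$age_probs)
  age <- ifelse(age_band == "18-64", round(stats::runif(n, 18, 64)),
                ifelse(age_band == ">64", round(stats::runif(n, 65, 90)), NA))
  wt_band <- sample(names(config$weight_probs), n, TRUE, config$weight_probs)
  wt <- ifelse(wt_band == "<50 kg", round(stats::runif(n, 40, 50), 1),
               ifelse(wt_band == "50-100 kg", round(stats::runif(n, 50, 100), 1),
                      ifelse(wt_band == ">100 kg", round(stats::runif(n, 100, 160), 1),
                             NA)))
  src <- sample(names(config$source_probs), n, TRUE, config$source_probs)
  src[src == "Unknown"] <- ""

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"),
    event_dt = degrade_dates(format(event_date, "%Y%m%d"),
                             config$partial_date_rate),
    sex = sex,
    age = ifelse(is.na(age), "", as.character(age)),
    age_cod = ifelse(is.na(age), "", "YR"),
    wt = ifelse(is.na(wt), "", as.character(wt)),
    wt_cod = ifelse(is.na(wt), "", "KG"),
    occp_cod = src, stringsAsFactors = FALSE)

  # drugs
  pool <- sim_drug_pool()
  syn <- synonym_table()
  primary_drug <- character(n)
  primary_drug[exposure %in% c("combination", "glp1ra_only")] <-
    sample(pool$glp1ra, sum(exposure %in% c("combination", "glp1ra_only")), TRUE)
  primary_drug[exposure == "metformin_only"] <- "metformin"
  primary_drug[exposure == "other"] <-
    sample(pool$other, sum(exposure == "other"), TRUE)
  drug_rows <- list(data.frame(
    primaryid = primaryid, caseid = caseid, drug_seq = "1", role_cod = "PS",
    drugname = verbatim_spelling(primary_drug, syn), stringsAsFactors = FALSE))
  comb <- which(exposure == "combination")
  if (length(comb)) {
    drug_rows[[2L]] <- data.frame(
      primaryid = primaryid[comb], caseid = caseid[comb], drug_seq = "2",
      role_cod = sample(c("C", "SS", "PS"), length(comb), TRUE,
                        prob = c(0.6, 0.25, 0.15)),
      drugname = verbatim_spelling(rep("metformin", length(comb)), syn),
      stringsAsFactors = FALSE)
  }
  conc <- which(stats::runif(n) < config$concomitant_rate)
  if (length(conc)) {
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      primaryid = primaryid[conc], caseid = caseid[conc], drug_seq = "3",
      role_cod = "C",
      drugname = toupper(sample(pool$concomitant, length(conc), TRUE)),
      stringsAsFactors = FALSE)
  }
  drug <- do.call(rbind, drug_rows)
  drug <- drug[order(drug$primaryid, drug$drug_seq), , drop = FALSE]
  rownames(drug) <- NULL

  # reactions: one background PT always, plus one PT per active term set
  term_sets <- default_term_sets()
  reac_rows <- list(data.frame(
    primaryid = primaryid, caseid = caseid,
    pt = sample(background_pts, n, TRUE), stringsAsFactors = FALSE))
  for (s in sets) {
    idx <- which(event[, s])
    if (length(idx)) {
      pts <- if (s %in% names(term_sets)) term_sets[[s]]$preferred_terms else s
      reac_rows[[length(reac_rows) + 1L]] <- data.frame(
        primaryid = primaryid[idx], caseid = caseid[idx],
        pt = sample(pts, length(idx), TRUE), stringsAsFactors = FALSE)
    }
  }
  reac <- do.call(rbind, reac_rows)
  reac <- reac[order(reac$primaryid), , drop = FALSE]
  rownames(reac) <- NULL

  # therapy start dates for the primary-suspect drug
  ther <- data.frame(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
    start_dt = degrade_dates(format(start_date, "%Y%m%d"),
                             config$partial_date_rate),
    stringsAsFactors = FALSE)
  # combination partner shares the start date (kept fully dated)
  if (length(comb)) {
    ther <- rbind(ther, data.frame(
      primaryid = primaryid[comb], caseid = caseid[comb], dsg_drug_seq = "2",
      start_dt = format(start_date[comb], "%Y%m%d"), stringsAsFactors = FALSE))
    ther <- ther[order(ther$primaryid, ther$dsg_drug_seq), , drop = FALSE]
    rownames(ther) <- NULL
  }

  # serious outcome (single worst code; "Missing" emits no OUTC row)
  oc_rates <- config$outcome_rates
  outcome <- character(n)
  outcome[any_event] <- sample(names(oc_rates$event), sum(any_event), TRUE,
                               oc_rates$event)
  outcome[!any_event] <- sample(names(oc_rates$background), sum(!any_event),
                                TRUE, oc_rates$background)
  has_oc <- outcome != "Missing"
  outc <- data.frame(primaryid = primaryid[has_oc], caseid = caseid[has_oc],
                     outc_cod = outcome[has_oc], stringsAsFactors = FALSE)

  rpsr <- data.frame(primaryid = primaryid, caseid = caseid,
                     rpsr_cod = sample(c("EXP", "PER"), n, TRUE, c(0.7, 0.3)),
                     stringsAsFactors = FALSE)

  tables <- faers_tables(demo, drug, reac, ther, outc, rpsr)

  truth_rows <- rates
  mix <- config$exposure_mix[truth_rows$exposure]
  truth_rows$expected_event <- n * mix * truth_rows$rate
  truth_rows$expected_nonevent <- n * mix * (1 - truth_rows$rate)
  gt <- structure(list(
    n_reports = n,
    cells = truth_rows,
    assignments = data.frame(primaryid = primaryid, caseid = caseid,
                             exposure = exposure, tto_days = tto_true,
                             event, stringsAsFactors = FALSE),
    duplicate_caseids = character(0),
    config = config
  ), class = "sim_ground_truth")
  list(tables = tables, ground_truth = gt)
}

#' @export
print.sim_ground_truth <- function(x, ...) {
  cat("<sim_ground_truth> n_reports=", x$n_reports, ", duplicates=",
      length(x$duplicate_caseids), "\n", sep = "")
  print(ground_truth_summary(x))
  invisible(x)
}

#' Theoretical odds ratio implied by a configuration
#'
#' The odds ratio of event reporting between two exposure patterns for one
#' term set, computed from the configured (injected) rates — the estimand the
#' downstream ROR should recover.
#'
#' @param config a [sim_config()].
#' @param term_set term-set name.
#' @param target,comparator exposure patterns.
#' @return numeric odds ratio.
#' @export
theoretical_or <- function(config, term_set, target = "combination",
                           comparator = "glp1ra_only") {
  rates <- injected_rates(config)
  r <- function(ex) rates$rate[rates$exposure == ex & rates$term_set == term_set]
  (r(target) / (1 - r(target))) / (r(comparator) / (1 - r(comparator)))
}

#' Inject duplicate reports into a bundle
#'
#' Duplicates a random `rate` fraction of cases as near-copies: same
#' `caseid`, a new `primaryid`, and a later receipt date, emulating FAERS
#' follow-up submissions. The keep-latest [deduplicate()] rule therefore
#' keeps the injected copy.
#'
#' @param tables a [faers_tables] bundle.
#' @param rate fraction in `[0, 1)` of cases to duplicate.
#' @param seed integer seed.
#' @param ground_truth optional `sim_ground_truth` whose
#'   `duplicate_caseids` is filled in.
#' @return list with `tables` (augmented bundle) and `ground_truth`.
#' @export
inject_duplicates <- function(tables, rate, seed = 1L, ground_truth = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0 || nrow(tables$demo) == 0L) {
    if (!is.null(ground_truth)) ground_truth$duplicate_caseids <- character(0)
    return(list(tables = tables, ground_truth = ground_truth))
  }
  set.seed(seed)
  demo <- tables$demo
  n_dup <- round(rate * nrow(demo))
  pick <- sort(sample(seq_len(nrow(demo)), n_dup))
  dup_pid_old <- demo$primaryid[pick]
  dup_case <- demo$caseid[pick]
  new_pid <- paste0(dup_case, "2")

  new_demo <- demo[pick, , drop = FALSE]
  new_demo$primaryid <- new_pid
  lag <- sample(1:90, n_dup, replace = TRUE)
  new_demo$fda_dt <- format(as.Date(demo$fda_dt[pick], "%Y%m%d") + lag,
                            "%Y%m%d")
  out <- tables
  out$demo <- rbind(demo, new_demo)
  for (tab in c("drug", "reac", "ther", "outc", "rpsr")) {
    df <- tables[[tab]]
    copy <- df[df$primaryid %in% dup_pid_old, , drop = FALSE]
    if (nrow(copy)) {
      copy$primaryid <- new_pid[match(copy$primaryid, dup_pid_old)]
      out[[tab]] <- rbind(df, copy)
    }
  }
  validate_faers_tables(out)
  if (!is.null(ground_truth)) ground_truth$duplicate_caseids <- dup_case
  list(tables = out, ground_truth = ground_truth)
}

#' Tabular summary of simulation ground truth
#'
#' @param gt a `sim_ground_truth` from [generate_dataset()].
#' @return data.frame with one row per (exposure, term-set): `multiplier`,
#'   theoretical `rate`, `expected_event` and `expected_nonevent` counts at
#'   `n_reports`.
#' @export
ground_truth_summary <- function(gt) {
  stopifnot(inherits(gt, "sim_ground_truth"))
  out <- gt$cells
  rownames(out) <- NULL
  out
}

#' Split a bundle into quarterly bundles by receipt date
#'
#' @param tables a [faers_tables] bundle.
#' @return Named list of [faers_tables], one per observed `YYYYQn` quarter.
#' @export
split_quarters <- function(tables) {
  d <- parse_faers_date(tables$demo$fda_dt)
  q <- paste0(d$year, "Q", (d$month - 1) %/% 3 + 1)
  out <- list()
  for (lab in sort(unique(q))) {
    keep <- tables$demo$primaryid[q == lab]
    sub <- tables
    sub$demo <- tables$demo[q == lab, , drop = FALSE]
    for (tab in c("drug", "reac", "ther", "outc", "rpsr")) {
      sub[[tab]] <- tables[[tab]][tables[[tab]]$primaryid %in% keep, , drop = FALSE]
    }
    attr(sub, "quarter") <- lab
    out[[lab]] <- sub
  }
  out
}
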