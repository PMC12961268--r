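#' Exposure classification rule
#'
#' Defines how reports are assigned to exposure cohorts. The default mirrors
#' the study design: the target class (GLP-1 receptor agonists) must appear
#' as primary suspect (PS), while the partner (metformin) may carry any role
#' code, because spontaneous reports list combination partners under varying
#' roles.
#'
#' @param target_class,partner_class drug class tags (see [drug_classes()]).
#' @param target_roles roles that qualify the target drug (subset of PS/SS).
#' @param partner_roles roles that qualify the partner drug.
#' @return An object of class `exposure_rule`.
#' @export
exposure_rule <- function(target_class = "glp1ra", partner_class = "metformin",
                          target_roles = "PS",
                          partner_roles = c("PS", "SS", "C", "I")) {
  if (length(target_roles) == 0L || length(partner_roles) == 0L) {
    stop("role sets must be non-empty", call. = FALSE)
  }
  stopifnot(all(target_roles %in% c("PS", "SS")),
            all(partner_roles %in% c("PS", "SS", "C", "I")))
  structure(list(target_class = target_class, partner_class = partner_class,
                 target_roles = target_roles, partner_roles = partner_roles),
            class = "exposure_rule")
}

#' Classify reports into exposure cohorts
#'
#' Labels every report as one of `combination` (target class in a target
#' role and partner class present in a partner role), `glp1ra_only` (target
#' class in a target role, partner absent in any role), `metformin_only`
#' (partner class in a target role, target class absent in any role) or
#' `other`. The four labels are mutually exclusive and exhaustive.
#'
#' @param tables a [faers_tables] bundle whose DRUG table has been through
#'   [normalize_drugs()] (columns `canonical`, `class`).
#' @param rule an [exposure_rule].
#' @return data.frame with columns `primaryid`, `exposure`.
#' @export
classify_exposure <- function(tables, rule = exposure_rule()) {
  drug <- tables$drug
  if (!all(c("canonical", "class") %in% names(drug))) {
    stop("DRUG table lacks canonical/class columns; run normalize_drugs() first",
         call. = FALSE)
  }
  pids <- tables$demo$primaryid
  if (length(setdiff(pids, drug$primaryid))) {
    stop("report(s) with no drug records: ",
         paste(utils::head(setdiff(pids, drug$primaryid), 3), collapse = ", "),
         call. = FALSE)
  }
  is_target <- drug$class == rule$target_class
  is_partner <- drug$class == rule$partner_class
  target_in_role <- is_target & drug$role_cod %in% rule$target_roles
  partner_in_role <- is_partner & drug$role_cod %in% rule$partner_roles
  partner_target_role <- is_partner & drug$role_cod %in% rule$target_roles

  has <- function(flag) pids %in% unique(drug$primaryid[flag])
  t_role <- has(target_in_role)
  t_any <- has(is_target)
  p_role <- has(partner_in_role)
  p_any <- has(is_partner)
  p_trole <- has(partner_target_role)

  exposure <- rep("other", length(pids))
  exposure[t_role & p_role] <- "combination"
  exposure[t_role & !p_any & !(t_role & p_role)] <- "glp1ra_only"
  exposure[p_trole & !t_any] <- "metformin_only"
  data.frame(primaryid = pids, exposure = exposure, stringsAsFactors = FALSE)
}

#' Match reaction terms against a term set
#'
#' @param reactions character vector of preferred-term strings.
#' @param terms a [term_set].
#' @return list with `flag` (TRUE iff at least one reaction is in the set,
#'   case-insensitive exact match) and `matched` (the matching PTs,
#'   lower-cased).
#' @examples
#' match_terms(c("Suicidal ideation", "Nausea"),
#'             default_term_sets()$suicide_self_injury)
#' @export
match_terms <- function(reactions, terms) {
  stopifnot(inherits(terms, "term_set"))
  pts <- tolower(trimws(reactions))
  hit <- pts[pts %in% terms$preferred_terms]
  list(flag = length(hit) > 0L, matched = unique(hit))
}

#' Classify all reports against a term set
#'
#' @param tables a [faers_tables] bundle.
#' @param terms a [term_set].
#' @return data.frame with `primaryid`, logical `flag`, and `matched`
#'   (list-column of matching PTs).
#' @export
classify_event <- function(tables, terms) {
  stopifnot(inherits(terms, "term_set"))
  pids <- tables$demo$primaryid
  reac <- tables$reac
  pt <- tolower(trimws(reac$pt))
  in_set <- pt %in% terms$preferred_terms
  matched <- split(pt[in_set], factor(reac$primaryid[in_set], levels = pids))
  matched <- lapply(matched, unique)
  data.frame(primaryid = pids,
             flag = lengths(matched) > 0L,
             matched = I(unname(matched)),
             stringsAsFactors = FALSE)
}

# ranked worst-first so each report carries a single serious outcome
outcome_priority <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Build a per-report analysis frame
#'
#' Joins the six tables into one row per report with the derived fields the
#' descriptive and signal stages use: exposure label, one event flag per term
#' set, sex, age in years (from the FAERS age-unit code), weight in kg,
#' report source, the single most severe serious-outcome code (priority
#' DE > LT > HO > DS > CA > RI > OT, else `"Missing"`), and receipt year.
#'
#' @param tables a [faers_tables] bundle (drug names normalized).
#' @param rule an [exposure_rule].
#' @param term_sets named list of [term_set] objects.
#' @return data.frame, one row per report.
#' @export
report_frame <- function(tables, rule = exposure_rule(),
                         term_sets = default_term_sets()) {
  demo <- tables$demo
  out <- data.frame(primaryid = demo$primaryid, caseid = demo$caseid,
                    stringsAsFactors = FALSE)
  out$exposure <- classify_exposure(tables, rule)$exposure
  for (nm in names(term_sets)) {
    out[[paste0("event_", nm)]] <- classify_event(tables, term_sets[[nm]])$flag
  }
  out$sex <- ifelse(demo$sex %in% c("F", "M"), demo$sex, "Unknown")
  out$age_years <- normalize_age(demo$age, demo$age_cod)
  out$wt_kg <- normalize_weight(demo$wt, demo$wt_cod)
  out$source <- ifelse(demo$occp_cod %in% c("CN", "HP", "MD", "PH", "OT"),
                       demo$occp_cod, "Unknown")
  outc <- tables$outc
  oc <- outc[outc$outc_cod %in% outcome_priority, , drop = FALSE]
  worst <- vapply(split(oc$outc_cod, factor(oc$primaryid, levels = demo$primaryid)),
                  function(codes) {
                    if (!length(codes)) return("Missing")
                    outcome_priority[min(match(codes, outcome_priority))]
                  }, "")
  out$outcome <- unname(worst)
  out$year <- suppressWarnings(as.integer(substr(demo$fda_dt, 1, 4)))
  out
}

normalize_age <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25,
            HR = 1 / 8766)
  m <- mult[toupper(trimws(age_cod))]
  m[is.na(m) & !is.na(a) & trimws(age_cod) == ""] <- 1  # blank unit: assume years
  unname(a * m)
}

normalize_weight <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt))
  mult <- c(KG = 1, KGS = 1, LBS = 0.45359237, LB = 0.45359237)
  m <- mult[toupper(trimws(wt_cod))]
  m[is.na(m) & !is.na(w) & trimws(wt_cod) == ""] <- 1
  unname(w * m)
}

#' Compare two proportions on a 2x2 table
#'
#' Applies the pinned test-selection rule: Pearson chi-squared without
#' continuity correction when all four expected counts are at least 5,
#' otherwise the two-sided Fisher exact test (two-sided by summing all table
#' probabilities not exceeding the observed table's, the convention of
#' [stats::fisher.test()]).
#'
#' @param counts a 2x2 matrix or a length-4 vector `c(a, b, c, d)` read
#'   row-wise (rows = groups, columns = outcome present/absent).
#' @param test `"auto"` (the rule above), or force `"pearson"`/`"fisher"`.
#' @return list with `p_value`, `test` (`"pearson"`, `"fisher"` or
#'   `"not_computable"`) and `min_expected`.
#' @examples
#' compare_groups(c(14, 90, 34, 441))  # Pearson, p ~ 0.035
#' compare_groups(c(1, 46, 9, 541))    # Fisher, p ~ 0.562
#' @export
compare_groups <- function(counts, test = c("auto", "pearson", "fisher")) {
  test <- match.arg(test)
  m <- if (is.matrix(counts)) counts else matrix(counts, 2L, 2L, byrow = TRUE)
  stopifnot(dim(m) == c(2L, 2L))
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = NA_real_, test = "not_computable",
                min_expected = NA_real_))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_exp <- min(expected)
  if (test == "auto") test <- if (min_exp >= 5) "pearson" else "fisher"
  p <- if (test == "pearson") {
    stats::chisq.test(m, correct = FALSE)$p.value
  } else {
    stats::fisher.test(m)$p.value
  }
  list(p_value = p, test = test, min_expected = min_exp)
}

descr_band <- function(values, breaks, labels) {
  band <- rep("Unknown", length(values))
  ok <- !is.na(values)
  band[ok] <- as.character(cut(values[ok], breaks = breaks, labels = labels,
                               right = TRUE, include.lowest = TRUE))
  band[is.na(band)] <- "Unknown"
  band
}

#' Descriptive characteristics table for two exposure cohorts
#'
#' Tabulates sex, weight band (<50 / 50-100 / >100 kg / Unknown), age band
#' (<18 / 18-64 / >64 / Unknown), report source and serious outcome for the
#' event-positive reports of two cohorts, with counts and percentages of the
#' full cohort size (Unknown rows stay in the denominator). Each serious
#' outcome row gets a two-group comparison p-value via [compare_groups()]
#' (outcome present vs absent, target vs comparator cohort).
#'
#' @param frame a [report_frame()] data.frame.
#' @param event name of the event flag column suffix (a term-set name).
#' @param target,comparator exposure labels (default combination vs
#'   glp1ra_only).
#' @return data.frame with columns `characteristic`, `level`, `n_target`,
#'   `pct_target`, `n_comparator`, `pct_comparator`, `p_value`, `test`
#'   (p/test only on outcome rows).
#' @export
build_descriptive_table <- function(frame, event,
                                    target = "combination",
                                    comparator = "glp1ra_only") {
  flag_col <- paste0("event_", event)
  stopifnot(flag_col %in% names(frame))
  sub <- frame[frame[[flag_col]], , drop = FALSE]
  tgt <- sub[sub$exposure == target, , drop = FALSE]
  cmp <- sub[sub$exposure == comparator, , drop = FALSE]
  n_t <- nrow(tgt)
  n_c <- nrow(cmp)

  levels_of <- list(
    sex = c("Female", "Male", "Unknown"),
    weight = c("<50 kg", "50-100 kg", ">100 kg", "Unknown"),
    age = c("<18", "18-64", ">64", "Unknown"),
    source = c("CN", "HP", "MD", "PH", "OT", "Unknown"),
    outcome = c("DE", "DS", "HO", "LT", "OT", "Missing")
  )
  value_of <- function(df, char) {
    switch(char,
      sex = c(F = "Female", M = "Male", Unknown = "Unknown")[df$sex],
      weight = descr_band(df$wt_kg, c(-Inf, 50, 100, Inf),
                          c("<50 kg", "50-100 kg", ">100 kg")),
      age = descr_band(df$age_years, c(-Inf, 18, 64, Inf),
                       c("<18", "18-64", ">64")),
      source = df$source,
      outcome = ifelse(df$outcome %in% c("CA", "RI"), "OT", df$outcome)
    )
  }
  rows <- list()
  for (char in names(levels_of)) {
    lv <- levels_of[[char]]
    ct <- table(factor(value_of(tgt, char), levels = lv))
    cc <- table(factor(value_of(cmp, char), levels = lv))
    for (l in lv) {
      a <- as.integer(ct[[l]]); b <- as.integer(cc[[l]])
      p <- NA_real_; tn <- NA_character_
      if (char == "outcome" && l != "Missing" && n_t > 0 && n_c > 0) {
        res <- compare_groups(c(a, n_t - a, b, n_c - b))
        p <- res$p_value; tn <- res$test
      }
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = char, level = l,
        n_target = a,
        pct_target = if (n_t > 0) 100 * a / n_t else NA_real_,
        n_comparator = b,
        pct_comparator = if (n_c > 0) 100 * b / n_c else NA_real_,
        p_value = p, test = tn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_target") <- n_t
  attr(out, "n_comparator") <- n_c
  out
}
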