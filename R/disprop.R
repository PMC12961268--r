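#' 2x2 contingency table for disproportionality statistics
#'
#' Cell layout: `a` = target exposure with the target event, `b` = target
#' exposure with other events, `c` = comparator exposure with the target
#' event, `d` = comparator exposure with other events.
#'
#' @param a,b,c,d non-negative integer counts, not all zero.
#' @return An object of class `contingency_table` (list with a, b, c, d, n).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n <= 0) stop("table total must be positive", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      " (N=", x$n, ")\n", sep = "")
  invisible(x)
}

#' Build the 2x2 table for one event and two exposure cohorts
#'
#' @param frame a [report_frame()] data.frame.
#' @param event term-set name (its `event_` flag column must exist), or a
#'   logical vector aligned with `frame` rows for ad-hoc events (e.g. a
#'   single preferred term).
#' @param target,comparator distinct exposure labels; both cohorts must be
#'   non-empty.
#' @return A [contingency_table].
#' @export
build_contingency <- function(frame, event, target = "combination",
                              comparator = "glp1ra_only") {
  stopifnot(target != comparator)
  flag <- if (is.logical(event)) {
    stopifnot(length(event) == nrow(frame))
    event
  } else {
    col <- paste0("event_", event)
    stopifnot(col %in% names(frame))
    frame[[col]]
  }
  in_t <- frame$exposure == target
  in_c <- frame$exposure == comparator
  if (!any(in_t) || !any(in_c)) {
    stop("empty cohort: target n=", sum(in_t), ", comparator n=", sum(in_c),
         call. = FALSE)
  }
  contingency_table(sum(in_t & flag), sum(in_t & !flag),
                    sum(in_c & flag), sum(in_c & !flag))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/(bc); the 95% CI is `exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b +
#' 1/c + 1/d))`. No continuity correction is applied: any zero cell makes
#' the estimate non-estimable.
#'
#' @param table a [contingency_table].
#' @return list with `ror`, `ci_low`, `ci_high`, `estimable`.
#' @export
compute_ror <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                estimable = FALSE))
  }
  ror <- (table$a * table$d) / (table$b * table$c)
  se <- sqrt(sum(1 / cells))
  list(ror = ror,
       ci_low = exp(log(ror) - 1.96 * se),
       ci_high = exp(log(ror) + 1.96 * se),
       estimable = TRUE)
}

#' Information component (IC) and its lower bound IC025
#'
#' The IC is the log2 observed-to-expected reporting ratio with expected
#' count `E = (a+b)(a+c)/N`.
#'
#' Methods:
#' * `"shrinkage"` (default): `IC = log2((a + 0.5) / (E + 0.5))`; `IC025` is
#'   the log2 of the 2.5% quantile of the gamma posterior with shape
#'   `a + 0.5` and rate `E + 0.5` — the standard credibility-interval form
#'   used in modern Bayesian disproportionality monitoring.
#' * `"plain"`: `IC = log2(a * N / ((a+c)(a+b)))` with `IC025 = IC - 2 * SD`
#'   where `SD = (1/ln 2) * sqrt(1/a)`, a delta-method approximation to the
#'   posterior spread; requires `a > 0`.
#'
#' @param table a [contingency_table].
#' @param method `"shrinkage"` or `"plain"`.
#' @return list with `ic`, `ic_sd` (`NA` for shrinkage), `ic025`,
#'   `method`, `estimable`.
#' @export
compute_ic <- function(table, method = c("shrinkage", "plain")) {
  stopifnot(inherits(table, "contingency_table"))
  method <- match.arg(method)
  a <- table$a
  e <- (a + table$b) * (a + table$c) / table$n
  if (method == "plain") {
    if (a == 0 || e == 0) {
      return(list(ic = NA_real_, ic_sd = NA_real_, ic025 = NA_real_,
                  method = method, estimable = FALSE))
    }
    ic <- log2(a / e)
    ic_sd <- sqrt(1 / a) / log(2)
    return(list(ic = ic, ic_sd = ic_sd, ic025 = ic - 2 * ic_sd,
                method = method, estimable = TRUE))
  }
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, rate = e + 0.5))
  list(ic = ic, ic_sd = NA_real_, ic025 = ic025, method = method,
       estimable = TRUE)
}

#' Full signal estimate for one 2x2 table
#'
#' Combines [compute_ror()], [compute_ic()] and the signal criteria into one
#' record.
#'
#' @param table a [contingency_table].
#' @param ic_method passed to [compute_ic()].
#' @return An object of class `signal_estimate`: list with the four cells,
#'   `n_cases` (= a), `ror`, `ror_ci_low`, `ror_ci_high`, `ic`, `ic_sd`,
#'   `ic025`, `ic_method`, `estimable` and `is_signal`.
#' @export
signal_estimate <- function(table, ic_method = c("shrinkage", "plain")) {
  ror <- compute_ror(table)
  ic <- compute_ic(table, ic_method)
  est <- structure(list(
    a = table$a, b = table$b, c = table$c, d = table$d,
    n_cases = table$a,
    ror = ror$ror, ror_ci_low = ror$ci_low, ror_ci_high = ror$ci_high,
    ic = ic$ic, ic_sd = ic$ic_sd, ic025 = ic$ic025, ic_method = ic$method,
    estimable = ror$estimable && ic$estimable,
    reason = NA_character_
  ), class = "signal_estimate")
  est$is_signal <- evaluate_signal(est)
  est
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat("<signal_estimate> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d, "\n",
      sep = "")
  if (isTRUE(x$estimable)) {
    cat(sprintf("  ROR %.2f (95%% CI %.2f-%.2f)  IC %.2f (IC025 %.2f, %s)\n",
                x$ror, x$ror_ci_low, x$ror_ci_high, x$ic, x$ic025, x$ic_method))
    cat("  signal:", x$is_signal, "\n")
  } else {
    cat("  non-estimable", if (!is.na(x$reason)) paste0(" (", x$reason, ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Apply the signal criteria
#'
#' A signal requires, jointly: at least 3 cases (`a >= 3`), the ROR 95% CI
#' lower limit above 1, and `IC025 > 0`.
#'
#' @param estimate a [signal_estimate()] (or any list with `n_cases`,
#'   `ror_ci_low`, `ic025`, `estimable`).
#' @return logical; `FALSE` when non-estimable.
#' @export
evaluate_signal <- function(estimate) {
  if (!isTRUE(estimate$estimable)) return(FALSE)
  estimate$n_cases >= 3 && estimate$ror_ci_low > 1 && estimate$ic025 > 0
}

#' Unmasking analysis: re-estimate after excluding reports with given drug classes
#'
#' Removes from both cohorts every report that contains (in any role) a drug
#' belonging to one of the excluded classes, then recomputes the 2x2 table
#' and signal statistics on the remainder. Used to check that a signal is
#' not carried by concomitant psychotropic or antidiabetic medication.
#'
#' @param tables a [faers_tables] bundle with normalized drug names.
#' @param frame the matching [report_frame()].
#' @param event term-set name.
#' @param exclude_classes character vector of class names (see
#'   [drug_classes()], [default_unmasking_classes()]).
#' @param target,comparator exposure labels.
#' @param ic_method passed to [compute_ic()].
#' @return A `signal_estimate`; non-estimable with `reason = "empty cohort"`
#'   when the exclusion empties either cohort.
#' @export
run_unmasking <- function(tables, frame, event, exclude_classes,
                          target = "combination", comparator = "glp1ra_only",
                          ic_method = c("shrinkage", "plain")) {
  drug <- tables$drug
  stopifnot("class" %in% names(drug))
  bad <- setdiff(exclude_classes, unique(drug_classes()$class))
  if (length(bad)) {
    stop("unknown drug class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  excluded_pids <- unique(drug$primaryid[drug$class %in% exclude_classes])
  keep <- !(frame$primaryid %in% excluded_pids)
  sub <- frame[keep, , drop = FALSE]
  if (!any(sub$exposure == target) || !any(sub$exposure == comparator)) {
    est <- structure(list(a = NA_integer_, b = NA_integer_, c = NA_integer_,
                          d = NA_integer_, n_cases = NA_integer_,
                          ror = NA_real_, ror_ci_low = NA_real_,
                          ror_ci_high = NA_real_, ic = NA_real_,
                          ic_sd = NA_real_, ic025 = NA_real_,
                          ic_method = match.arg(ic_method), estimable = FALSE,
                          reason = "empty cohort", is_signal = FALSE),
                     class = "signal_estimate")
    return(est)
  }
  tab <- build_contingency(sub, event, target, comparator)
  est <- signal_estimate(tab, ic_method)
  est$n_excluded <- sum(!keep)
  est
}

#' Sex-stratified subgroup analysis per preferred term
#'
#' For each PT of a term set, computes the signal estimate separately in the
#' female and male strata (reports of unknown sex are excluded from both)
#' and the male-to-female ratio of RORs (`NA` when either stratum is
#' non-estimable).
#'
#' @param tables a [faers_tables] bundle.
#' @param frame the matching [report_frame()].
#' @param terms a [term_set].
#' @param target,comparator exposure labels.
#' @param ic_method passed to [compute_ic()].
#' @return Long-format data.frame with columns `pt`, `sex`, the 2x2 cells,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `ic`, `ic025`, `estimable`,
#'   `is_signal`, `ratio_m_f` (repeated on both rows of a PT).
#' @export
sex_subgroup_analysis <- function(tables, frame, terms,
                                  target = "combination",
                                  comparator = "glp1ra_only",
                                  ic_method = c("shrinkage", "plain")) {
  stopifnot(inherits(terms, "term_set"))
  reac <- tables$reac
  pt_lc <- tolower(trimws(reac$pt))
  rows <- list()
  for (pt in terms$preferred_terms) {
    has_pt <- frame$primaryid %in% unique(reac$primaryid[pt_lc == pt])
    ests <- list()
    for (sx in c("F", "M")) {
      lab <- c(F = "Female", M = "Male")[[sx]]
      in_s <- frame$sex == sx
      sub <- frame[in_s, , drop = FALSE]
      flag <- has_pt[in_s]
      est <- tryCatch(
        signal_estimate(build_contingency(sub, flag, target, comparator),
                        ic_method),
        error = function(e) NULL)
      if (is.null(est)) {
        est <- list(a = NA_integer_, b = NA_integer_, c = NA_integer_,
                    d = NA_integer_, ror = NA_real_, ror_ci_low = NA_real_,
                    ror_ci_high = NA_real_, ic = NA_real_, ic025 = NA_real_,
                    estimable = FALSE, is_signal = FALSE)
      }
      ests[[lab]] <- est
    }
    ratio <- if (isTRUE(ests$Male$estimable) && isTRUE(ests$Female$estimable)) {
      ests$Male$ror / ests$Female$ror
    } else NA_real_
    for (lab in c("Female", "Male")) {
      e <- ests[[lab]]
      rows[[length(rows) + 1L]] <- data.frame(
        pt = pt, sex = lab, a = e$a, b = e$b, c = e$c, d = e$d,
        ror = e$ror, ror_ci_low = e$ror_ci_low, ror_ci_high = e$ror_ci_high,
        ic = e$ic, ic025 = e$ic025, estimable = isTRUE(e$estimable),
        is_signal = isTRUE(e$is_signal), ratio_m_f = ratio,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tabulate signal estimates for a set of term sets and PTs
#'
#' Convenience wrapper producing one row per term set (and optionally per
#' PT within each set) with the full signal statistics.
#'
#' @param tables a [faers_tables] bundle.
#' @param frame the matching [report_frame()].
#' @param term_sets named list of [term_set]s.
#' @param per_pt also compute one row per preferred term.
#' @param target,comparator exposure labels.
#' @param ic_method passed to [compute_ic()].
#' @return data.frame with columns `term_set`, `pt` (`NA` on set-level rows),
#'   cells, ROR/CI, IC/IC025, `ic_method`, `estimable`, `is_signal`.
#' @export
signal_table <- function(tables, frame, term_sets = default_term_sets(),
                         per_pt = FALSE, target = "combination",
                         comparator = "glp1ra_only",
                         ic_method = c("shrinkage", "plain")) {
  reac <- tables$reac
  pt_lc <- tolower(trimws(reac$pt))
  one <- function(set_name, pt, flag) {
    e <- tryCatch(
      signal_estimate(build_contingency(frame, flag, target, comparator),
                      ic_method),
      error = function(err) NULL)
    if (is.null(e)) return(NULL)
    data.frame(term_set = set_name, pt = if (is.null(pt)) NA_character_ else pt,
               a = e$a, b = e$b, c = e$c, d = e$d,
               ror = e$ror, ror_ci_low = e$ror_ci_low,
               ror_ci_high = e$ror_ci_high, ic = e$ic, ic025 = e$ic025,
               ic_method = e$ic_method, estimable = e$estimable,
               is_signal = e$is_signal, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nm in names(term_sets)) {
    rows[[length(rows) + 1L]] <- one(nm, NULL, frame[[paste0("event_", nm)]])
    if (per_pt) {
      for (pt in term_sets[[nm]]$preferred_terms) {
        flag <- frame$primaryid %in% unique(reac$primaryid[pt_lc == pt])
        rows[[length(rows) + 1L]] <- one(nm, pt, flag)
      }
    }
  }
  do.call(rbind, rows)
}
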