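#' Extract time-to-onset samples from a report bundle
#'
#' Time-to-onset (TTO) is the number of days from the earliest fully dated
#' therapy start of a target-class drug to the report's event date. Reports
#' are excluded (with a reason) when either date is missing or partial, or
#' when the difference is not positive.
#'
#' @param tables a [faers_tables] bundle with normalized drug names.
#' @param target_class drug class whose therapy start anchors the interval
#'   (default `"glp1ra"`; use `"metformin"` for the metformin cohorts).
#' @return data.frame with `primaryid`, `tto_days` (integer, `NA` when
#'   excluded), `included` and `reason` (`NA` when included; otherwise
#'   `"no start date"`, `"partial date"`, `"missing event date"` or
#'   `"non-positive TTO"`).
#' @export
extract_tto <- function(tables, target_class = "glp1ra") {
  drug <- tables$drug
  stopifnot("class" %in% names(drug))
  demo <- tables$demo
  ther <- tables$ther
  # therapy rows of target-class drugs, joined on (primaryid, drug_seq)
  key_d <- paste(drug$primaryid, drug$drug_seq, sep = "\r")
  key_t <- paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r")
  tgt <- ther[key_t %in% key_d[drug$class == target_class], , drop = FALSE]
  start <- parse_faers_date(tgt$start_dt)
  has_any_start <- demo$primaryid %in% tgt$primaryid[nzchar(trimws(tgt$start_dt))]
  full <- start$precision == "day"
  earliest <- rep(as.Date(NA), nrow(demo))
  if (any(full)) {
    by_pid <- split(start$date[full], factor(tgt$primaryid[full],
                                             levels = demo$primaryid))
    got <- lengths(by_pid) > 0L
    earliest[got] <- as.Date(vapply(by_pid[got], min, numeric(1)),
                             origin = "1970-01-01")
  }
  ev <- parse_faers_date(demo$event_dt)

  reason <- rep(NA_character_, nrow(demo))
  reason[ev$precision %in% c("year", "month")] <- "partial date"
  reason[ev$precision == "missing"] <- "missing event date"
  no_start <- is.na(earliest) & is.na(reason)
  reason[no_start & has_any_start] <- "partial date"
  reason[no_start & !has_any_start] <- "no start date"
  tto <- as.integer(ev$date - earliest)
  reason[is.na(reason) & tto <= 0] <- "non-positive TTO"
  included <- is.na(reason)
  data.frame(primaryid = demo$primaryid,
             tto_days = ifelse(included, tto, NA_integer_),
             included = included, reason = reason,
             stringsAsFactors = FALSE)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param x numeric vector, `n >= 1`.
#' @return list with `median`, `q25`, `q75`, `n`.
#' @export
median_iqr <- function(x) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[[2L]], q25 = q[[1L]], q75 = q[[3L]], n = length(x))
}

# profile score equation for the Weibull shape given data x
weibull_shape_score <- function(b, x, mean_log) {
  xb <- x^b
  sum(xb * log(x)) / sum(xb) - 1 / b - mean_log
}

weibull_negll <- function(par, x) {
  # par = (log alpha, log beta)
  a <- exp(par[[1L]]); b <- exp(par[[2L]])
  -(length(x) * (log(b) - b * log(a)) + (b - 1) * sum(log(x)) -
      sum((x / a)^b))
}

#' Two-parameter Weibull maximum-likelihood fit
#'
#' Fits scale `alpha` and shape `beta` by profile likelihood: the shape
#' solves the one-dimensional score equation (root-found with
#' [stats::uniroot()]) and the scale then has the closed form
#' `(mean(x^beta))^(1/beta)`. 95% CIs are Wald intervals on the log
#' parameters from the observed information matrix, exponentiated so the
#' bounds stay positive. No censoring is supported.
#'
#' @param x positive numeric sample, `n >= 3`, at least two distinct values.
#' @return An object of class `weibull_fit`: list with `n`, `scale_alpha`,
#'   `scale_ci_low`, `scale_ci_high`, `shape_beta`, `shape_ci_low`,
#'   `shape_ci_high`, `median_days`, `q25`, `q75`, `failure_type`,
#'   `converged`.
#' @examples
#' set.seed(1)
#' fit_weibull(rweibull(200, shape = 0.7, scale = 80))
#' @export
fit_weibull <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("sample must be positive and finite", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  mean_log <- mean(log(x))
  lo <- 1e-3; hi <- 1
  while (weibull_shape_score(hi, x, mean_log) < 0 && hi < 1e3) hi <- hi * 2
  if (hi >= 1e3) stop("shape root-find failed to bracket", call. = FALSE)
  root <- stats::uniroot(weibull_shape_score, c(lo, hi), x = x,
                         mean_log = mean_log, tol = 1e-10)
  beta <- root$root
  alpha <- mean(x^beta)^(1 / beta)

  hess <- stats::optimHess(c(log(alpha), log(beta)), weibull_negll, x = x)
  vcov <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vcov) || any(diag(vcov) <= 0)) {
    stop("non-convergence: observed information not positive definite ",
         "(n=", length(x), ", shape=", signif(beta, 4), ")", call. = FALSE)
  }
  se <- sqrt(diag(vcov))
  ci <- function(est, s) c(est * exp(-1.96 * s), est * exp(1.96 * s))
  a_ci <- ci(alpha, se[[1L]])
  b_ci <- ci(beta, se[[2L]])
  mq <- median_iqr(x)
  structure(list(
    n = length(x),
    scale_alpha = alpha, scale_ci_low = a_ci[[1L]], scale_ci_high = a_ci[[2L]],
    shape_beta = beta, shape_ci_low = b_ci[[1L]], shape_ci_high = b_ci[[2L]],
    median_days = mq$median, q25 = mq$q25, q75 = mq$q75,
    failure_type = classify_failure_type(beta, b_ci[[1L]], b_ci[[2L]]),
    converged = TRUE
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d  median %.1f (IQR %.1f-%.1f)\n  scale %.2f (%.2f-%.2f)  shape %.2f (%.2f-%.2f)  %s\n",
    x$n, x$median_days, x$q25, x$q75, x$scale_alpha, x$scale_ci_low,
    x$scale_ci_high, x$shape_beta, x$shape_ci_low, x$shape_ci_high,
    x$failure_type))
  invisible(x)
}

#' Classify the hazard profile from the Weibull shape parameter
#'
#' The Weibull shape parameter test reads the hazard over time off the shape
#' `beta` and its 95% CI: `early` failure (decreasing hazard) when the CI
#' lies entirely below 1, `wear_out` (increasing hazard) when it lies
#' entirely above 1, and `random` (roughly constant hazard) whenever the CI
#' contains 1.
#'
#' @param shape_beta point estimate.
#' @param ci_low,ci_high 95% CI bounds, `0 < ci_low <= shape_beta <= ci_high`.
#' @return `"early"`, `"random"` or `"wear_out"`.
#' @examples
#' classify_failure_type(0.69, 0.60, 0.79)  # early
#' classify_failure_type(0.81, 0.48, 1.14)  # random
#' @export
classify_failure_type <- function(shape_beta, ci_low, ci_high) {
  if (!(ci_low > 0 && ci_low <= shape_beta && shape_beta <= ci_high)) {
    stop("invalid CI: need 0 < ci_low <= shape <= ci_high", call. = FALSE)
  }
  if (ci_high < 1) "early" else if (ci_low > 1) "wear_out" else "random"
}

#' Onset-interval histogram
#'
#' Bins TTO samples into the first month (1-30 days), months 1-3 (31-90),
#' months 3-6 (91-180) and beyond 6 months (>180), with percentages of the
#' sample size.
#'
#' @param x positive TTO values in days, `n >= 1`.
#' @return data.frame with `bin`, `count`, `percent`.
#' @export
onset_histogram <- function(x) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  stopifnot(all(x >= 1))
  bins <- cut(x, breaks = c(0, 30, 90, 180, Inf),
              labels = c("1-30", "31-90", "91-180", ">180"))
  counts <- table(bins)
  data.frame(bin = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(x),
             stringsAsFactors = FALSE)
}

#' Rank-based comparison of two TTO samples
#'
#' Two-sided Wilcoxon rank-sum test of the TTO distributions of two groups.
#'
#' @param x,y positive numeric samples.
#' @return list with `p_value` and `test = "wilcoxon_rank_sum"`.
#' @export
compare_tto <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(p_value = p, test = "wilcoxon_rank_sum")
}
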