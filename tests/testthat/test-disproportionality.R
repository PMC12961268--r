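test_that("ROR and its CI follow the 2x2 definition", {
  # cells reconstructed from the published cohort totals
  # (2,634 / 40,841 reports; 104 / 475 suicide events)
  r <- compute_ror(contingency_table(104, 2530, 475, 40366))
  expect_equal(r$ror, 104 * 40366 / (2530 * 475), tolerance = 1e-12)
  expect_equal(r$ror, 3.49, tolerance = 0.002)
  expect_true(r$estimable)
  se <- sqrt(1 / 104 + 1 / 2530 + 1 / 475 + 1 / 40366)
  expect_equal(r$ci_low, exp(log(r$ror) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(r$ror) + 1.96 * se))

  flat <- compute_ror(contingency_table(10, 90, 10, 90))
  expect_equal(flat$ror, 1)
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)

  z <- compute_ror(contingency_table(0, 10, 5, 100))
  expect_false(z$estimable)
  expect_true(is.na(z$ror))
})

test_that("ROR is invariant to row/column scaling; IC is not", {
  base <- contingency_table(12, 88, 30, 870)
  r0 <- compute_ror(base)$ror
  # scale the comparator row by 3
  expect_equal(compute_ror(contingency_table(12, 88, 90, 2610))$ror, r0)
  # scale the event column by 4
  expect_equal(compute_ror(contingency_table(48, 88, 120, 870))$ror, r0)
  ic0 <- compute_ic(base, "plain")$ic
  expect_false(isTRUE(all.equal(
    compute_ic(contingency_table(12, 88, 90, 2610), "plain")$ic, ic0)))
})

test_that("ROR CI narrows as all cells scale up", {
  width <- sapply(c(1, 2, 5, 10), function(k) {
    r <- compute_ror(contingency_table(5 * k, 95 * k, 20 * k, 880 * k))
    log(r$ci_high) - log(r$ci_low)
  })
  expect_true(all(diff(width) < 0))
})

test_that("plain IC evaluates the log2 observed/expected formula", {
  # proportional table: observed equals expected
  p0 <- compute_ic(contingency_table(10, 90, 100, 900), "plain")
  expect_equal(p0$ic, 0)
  p1 <- compute_ic(contingency_table(20, 80, 100, 900), "plain")
  expect_equal(p1$ic, log2(20 * 1100 / (120 * 100)))
  expect_equal(p1$ic, 0.874, tolerance = 1e-3)
  expect_equal(p1$ic_sd, sqrt(1 / 20) / log(2))
  expect_equal(p1$ic025, p1$ic - 2 * p1$ic_sd)
  expect_false(compute_ic(contingency_table(0, 10, 5, 100), "plain")$estimable)
})

test_that("IC025 sits below IC for both methods on random tables", {
  set.seed(7)
  for (i in 1:40) {
    tab <- contingency_table(rpois(1, 15) + 1, rpois(1, 80) + 1,
                             rpois(1, 40) + 1, rpois(1, 700) + 1)
    for (m in c("plain", "shrinkage")) {
      ic <- compute_ic(tab, m)
      expect_lt(ic$ic025, ic$ic)
    }
  }
})

test_that("shrinkage IC approaches plain IC as counts grow at fixed ratios", {
  deltas <- sapply(c(1, 10, 100, 1000), function(k) {
    tab <- contingency_table(20 * k, 80 * k, 100 * k, 900 * k)
    abs(compute_ic(tab, "shrinkage")$ic - compute_ic(tab, "plain")$ic)
  })
  expect_true(all(diff(deltas) < 0))
  expect_lt(deltas[4], 1e-3)
})

test_that("signal criteria are a conjunction and monotone in a", {
  mk <- function(n_cases, ci_low, ic025) {
    list(n_cases = n_cases, ror_ci_low = ci_low, ic025 = ic025,
         estimable = TRUE)
  }
  expect_false(evaluate_signal(mk(2, 2.0, 1.0)))   # too few cases
  expect_true(evaluate_signal(mk(5, 1.01, 0.01)))
  expect_false(evaluate_signal(mk(5, 0.99, 0.2)))  # ROR CI fails
  expect_false(evaluate_signal(mk(5, 1.5, -0.1)))  # IC025 fails

  # increasing a with b, c, d fixed never turns a signal off
  b <- 80; cc <- 50; d <- 900
  flags <- sapply(1:60, function(a) {
    evaluate_signal(signal_estimate(contingency_table(a, b, cc, d)))
  })
  expect_false(any(diff(flags) < 0))
})

test_that("contingency construction conserves cohort sizes", {
  frame <- data.frame(
    exposure = rep(c("combination", "glp1ra_only"), c(10, 90)),
    stringsAsFactors = FALSE)
  frame$event_x <- rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 7, 5, 85))
  tab <- build_contingency(frame, "x")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3, 7, 5, 85))
  expect_equal(tab$a + tab$b, 10)
  expect_equal(tab$c + tab$d, 90)
  expect_error(build_contingency(frame[frame$exposure == "glp1ra_only", ], "x"),
               "empty cohort")
})

test_that("unmasking excludes reports with listed drug classes and recomputes", {
  # 10 combination + 100 comparator reports; 4 of the combination carry a
  # psychotropic drug and must leave both cells
  n_t <- 10; n_c <- 100
  pid <- as.character(seq_len(n_t + n_c))
  frame <- data.frame(
    primaryid = pid, caseid = pid,
    exposure = rep(c("combination", "glp1ra_only"), c(n_t, n_c)),
    stringsAsFactors = FALSE)
  frame$event_x <- rep(FALSE, n_t + n_c)
  frame$event_x[c(1:4, 11:15)] <- TRUE  # 4/10 target, 5/100 comparator
  drug <- data.frame(
    primaryid = pid, caseid = pid, drug_seq = "1", role_cod = "PS",
    drugname = "GLIMEPIRIDE", canonical = "glimepiride",
    class = "sulfonylureas", stringsAsFactors = FALSE)
  # reports 1, 2 (events) and 5, 6 (non-events) carry sertraline
  extra <- drug[c(1, 2, 5, 6), ]
  extra$drug_seq <- "2"; extra$role_cod <- "C"
  extra$canonical <- "sertraline"; extra$class <- "antidepressants"
  demo <- data.frame(primaryid = pid, caseid = pid, fda_dt = "20200101",
                     event_dt = "", sex = "F", age = "", age_cod = "",
                     wt = "", wt_cod = "", occp_cod = "CN",
                     stringsAsFactors = FALSE)
  empty <- data.frame(primaryid = character(0), caseid = character(0),
                      stringsAsFactors = FALSE)
  tables <- faers_tables(demo, rbind(drug, extra),
                         cbind(empty, pt = character(0)),
                         cbind(empty, dsg_drug_seq = character(0),
                               start_dt = character(0)),
                         cbind(empty, outc_cod = character(0)),
                         cbind(empty, rpsr_cod = character(0)))

  est <- run_unmasking(tables, frame, "x", "antidepressants")
  # remaining: target 2 events / 4 non-events, comparator untouched at 5 / 95
  expect_equal(c(est$a, est$b, est$c, est$d), c(2, 4, 5, 95))
  expect_equal(est$ror, (2 * 95) / (4 * 5))
  expect_equal(est$n_excluded, 4)

  # excluding a class nobody took is a no-op
  base <- signal_estimate(build_contingency(frame, "x"))
  noop <- run_unmasking(tables, frame, "x", "opioids")
  expect_equal(noop$ror, base$ror)
  expect_equal(c(noop$a, noop$b, noop$c, noop$d),
               c(base$a, base$b, base$c, base$d))

  # excluding everything empties the cohorts
  all_cls <- run_unmasking(tables, frame, "x", "sulfonylureas")
  expect_false(all_cls$estimable)
  expect_equal(all_cls$reason, "empty cohort")
  expect_error(run_unmasking(tables, frame, "x", "no_such_class"),
               "unknown drug class")
})

test_that("sex subgroup RORs and the male/female ratio match hand arithmetic", {
  # hand-built strata: M (6,94,10,490), F (3,97,10,490) for one PT
  mk_stratum <- function(sex, a, b, c, d, offset) {
    n <- a + b + c + d
    pid <- as.character(offset + seq_len(n))
    data.frame(primaryid = pid, caseid = pid,
               exposure = rep(c("combination", "glp1ra_only"), c(a + b, c + d)),
               sex = sex,
               has_pt = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
               stringsAsFactors = FALSE)
  }
  fr <- rbind(mk_stratum("M", 6, 94, 10, 490, 0),
              mk_stratum("F", 3, 97, 10, 490, 1000),
              mk_stratum("Unknown", 5, 5, 5, 5, 5000))  # must be ignored
  reac <- data.frame(primaryid = fr$primaryid[fr$has_pt],
                     caseid = fr$primaryid[fr$has_pt],
                     pt = "Suicidal ideation", stringsAsFactors = FALSE)
  demo <- data.frame(primaryid = fr$primaryid, caseid = fr$caseid,
                     fda_dt = "20200101", event_dt = "", sex = fr$sex,
                     age = "", age_cod = "", wt = "", wt_cod = "",
                     occp_cod = "CN", stringsAsFactors = FALSE)
  empty <- data.frame(primaryid = character(0), caseid = character(0))
  drug <- data.frame(primaryid = fr$primaryid, caseid = fr$caseid,
                     drug_seq = "1", role_cod = "PS", drugname = "x",
                     canonical = "x", class = "other",
                     stringsAsFactors = FALSE)
  tables <- faers_tables(demo, drug, reac,
                         cbind(empty, dsg_drug_seq = character(0),
                               start_dt = character(0)),
                         cbind(empty, outc_cod = character(0)),
                         cbind(empty, rpsr_cod = character(0)))
  ts <- term_set("t", "suicidal ideation")
  res <- sex_subgroup_analysis(tables, fr, ts)
  m <- res[res$sex == "Male", ]
  f <- res[res$sex == "Female", ]
  expect_equal(c(m$a, m$b, m$c, m$d), c(6, 94, 10, 490))
  ror_m <- 6 * 490 / (94 * 10)
  ror_f <- 3 * 490 / (97 * 10)
  expect_equal(m$ror, ror_m)
  expect_equal(f$ror, ror_f)
  expect_equal(unique(res$ratio_m_f), ror_m / ror_f)

  # symmetric rates give ratio ~ 1
  fr2 <- rbind(mk_stratum("M", 5, 95, 10, 490, 0),
               mk_stratum("F", 5, 95, 10, 490, 1000))
  reac2 <- data.frame(primaryid = fr2$primaryid[fr2$has_pt],
                      caseid = fr2$primaryid[fr2$has_pt],
                      pt = "Suicidal ideation", stringsAsFactors = FALSE)
  demo2 <- demo[seq_len(nrow(fr2)), ]
  demo2$primaryid <- fr2$primaryid; demo2$caseid <- fr2$caseid
  demo2$sex <- fr2$sex
  drug2 <- drug[seq_len(nrow(fr2)), ]
  drug2$primaryid <- fr2$primaryid; drug2$caseid <- fr2$caseid
  tables2 <- faers_tables(demo2, drug2, reac2,
                          cbind(empty, dsg_drug_seq = character(0),
                                start_dt = character(0)),
                          cbind(empty, outc_cod = character(0)),
                          cbind(empty, rpsr_cod = character(0)))
  res2 <- sex_subgroup_analysis(tables2, fr2, ts)
  expect_equal(unique(res2$ratio_m_f), 1)

  # no male cases -> male non-estimable, ratio NA
  fr3 <- rbind(mk_stratum("M", 0, 100, 10, 490, 0),
               mk_stratum("F", 3, 97, 10, 490, 1000))
  reac3 <- data.frame(primaryid = fr3$primaryid[fr3$has_pt],
                      caseid = fr3$primaryid[fr3$has_pt],
                      pt = "Suicidal ideation", stringsAsFactors = FALSE)
  demo3 <- demo[seq_len(nrow(fr3)), ]
  demo3$primaryid <- fr3$primaryid; demo3$caseid <- fr3$caseid
  demo3$sex <- fr3$sex
  drug3 <- drug[seq_len(nrow(fr3)), ]
  drug3$primaryid <- fr3$primaryid; drug3$caseid <- fr3$caseid
  tables3 <- faers_tables(demo3, drug3, reac3,
                          cbind(empty, dsg_drug_seq = character(0),
                                start_dt = character(0)),
                          cbind(empty, outc_cod = character(0)),
                          cbind(empty, rpsr_cod = character(0)))
  res3 <- sex_subgroup_analysis(tables3, fr3, ts)
  expect_false(res3$estimable[res3$sex == "Male"])
  expect_true(all(is.na(res3$ratio_m_f)))
})
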