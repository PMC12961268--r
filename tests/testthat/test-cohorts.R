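test_that("shipped SMQ term sets carry the exact narrow PT lists", {
  ts <- default_term_sets()
  expect_setequal(names(ts), c("depression_ex_suicide", "suicide_self_injury"))
  expect_length(ts$depression_ex_suicide$preferred_terms, 12L)
  expect_length(ts$suicide_self_injury$preferred_terms, 9L)
  expect_true(all(c("depressed mood", "perinatal depression", "anhedonia") %in%
                    ts$depression_ex_suicide$preferred_terms))
  expect_true(all(c("completed suicide", "suicide threat", "intentional overdose") %in%
                    ts$suicide_self_injury$preferred_terms))
  expect_false("suicidal ideation" %in% ts$depression_ex_suicide$preferred_terms)
})

test_that("exposure classification follows the role-code rule and partitions reports", {
  b <- normalize_drugs(deduplicate(mini_bundle()))
  cls <- classify_exposure(b)
  got <- setNames(cls$exposure, b$demo$caseid)
  expect_equal(unname(got[c("C0000001", "C0000002", "C0000003", "C0000004")]),
               c("combination", "glp1ra_only", "other", "metformin_only"))
  expect_true(all(cls$exposure %in%
                    c("combination", "glp1ra_only", "metformin_only", "other")))
  expect_equal(nrow(cls), nrow(b$demo))

  # a report with no drug rows is an error
  b2 <- b
  b2$drug <- b2$drug[b2$drug$primaryid != "21", , drop = FALSE]
  expect_error(classify_exposure(b2), "no drug records")
})

test_that("event classification matches PTs case-insensitively", {
  ts <- default_term_sets()
  m <- match_terms(c("Suicidal ideation", "Nausea"), ts$suicide_self_injury)
  expect_true(m$flag)
  expect_equal(m$matched, "suicidal ideation")
  expect_true(match_terms("Depressed mood", ts$depression_ex_suicide)$flag)
  expect_false(match_terms("Nausea", ts$depression_ex_suicide)$flag)
  expect_false(match_terms("Nausea", ts$suicide_self_injury)$flag)

  b <- deduplicate(mini_bundle())
  ev <- classify_event(b, ts$suicide_self_injury)
  expect_equal(ev$flag, c("C0000001" = TRUE, "C0000002" = FALSE,
                          "C0000003" = FALSE, "C0000004" = FALSE)[b$demo$caseid],
               ignore_attr = TRUE)
})

test_that("test selection: Pearson uncorrected iff all expected >= 5, else prob-mass Fisher", {
  # suicide hospitalization row: expected >= 5 -> Pearson
  r1 <- compare_groups(c(14, 90, 34, 441))
  expect_equal(r1$test, "pearson")
  expect_equal(r1$p_value, 0.035, tolerance = 0.015)
  # depression death row: min expected < 5 -> Fisher
  r2 <- compare_groups(c(1, 46, 9, 541))
  expect_equal(r2$test, "fisher")
  expect_equal(r2$p_value, 0.562, tolerance = 0.002)
  # identical proportions
  expect_equal(compare_groups(c(10, 90, 10, 90))$p_value, 1)
  # zero margin -> not computable
  r0 <- compare_groups(c(0, 0, 5, 10))
  expect_equal(r0$test, "not_computable")
  expect_true(is.na(r0$p_value))
  expect_error(compare_groups(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Pearson p is invariant to swapping rows and columns", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rpois(4, 40) + 5, 2)
    p <- compare_groups(m, test = "pearson")$p_value
    expect_equal(compare_groups(m[2:1, ], test = "pearson")$p_value, p)
    expect_equal(compare_groups(m[, 2:1], test = "pearson")$p_value, p)
  }
})

test_that("descriptive table reproduces printed cohort percentages", {
  tb <- build_descriptive_table(published_suicide_cohorts(), "suicide_self_injury")
  expect_equal(attr(tb, "n_target"), 104L)
  expect_equal(attr(tb, "n_comparator"), 475L)
  de <- getrow(tb, "outcome", "DE")
  expect_equal(de$pct_target, 38.5, tolerance = 0.002)
  expect_equal(de$pct_comparator, 12.4, tolerance = 0.002)
  male <- getrow(tb, "sex", "Male")
  expect_equal(male$pct_target, 59.6, tolerance = 0.002)

  td <- build_descriptive_table(published_depression_cohorts(), "depression_ex_suicide")
  fem <- getrow(td, "sex", "Female")
  expect_equal(fem$pct_comparator, 67.3, tolerance = 0.002)

  # degenerate one-report cohort: 100%
  one <- cohort_fixture_frame("x", list(sex = c(1, 0, 0), outcome = c(1, 0, 0, 0, 0, 0)),
                      list(sex = c(1, 0, 0), outcome = c(0, 0, 0, 0, 0, 1)))
  t1 <- build_descriptive_table(one, "x")
  expect_equal(getrow(t1, "outcome", "DE")$pct_target, 100)
})

test_that("descriptive percentages per characteristic sum to 100 of the cohort", {
  tb <- build_descriptive_table(published_suicide_cohorts(), "suicide_self_injury")
  for (char in unique(tb$characteristic)) {
    block <- tb[tb$characteristic == char, ]
    expect_equal(sum(block$pct_target), 100, tolerance = 1e-9)
    expect_equal(sum(block$n_target), attr(tb, "n_target"))
    expect_equal(sum(block$n_comparator), attr(tb, "n_comparator"))
  }
})

test_that("descriptive outcome rows carry the pinned-rule p-values", {
  tb <- build_descriptive_table(published_suicide_cohorts(), "suicide_self_injury")
  ho <- getrow(tb, "outcome", "HO")
  expect_equal(ho$test, "pearson")
  expect_equal(ho$p_value, 0.035, tolerance = 0.015)
  lt <- getrow(tb, "outcome", "LT")
  expect_equal(lt$p_value, 0.227, tolerance = 0.005)
  de <- getrow(tb, "outcome", "DE")
  expect_lt(de$p_value, 0.001)
  td <- build_descriptive_table(published_depression_cohorts(), "depression_ex_suicide")
  expect_equal(getrow(td, "outcome", "DE")$test, "fisher")
  expect_equal(getrow(td, "outcome", "DE")$p_value, 0.562, tolerance = 0.002)
})

test_that("age and weight normalize from FAERS unit codes", {
  b <- deduplicate(mini_bundle())
  b <- normalize_drugs(b)
  fr <- report_frame(b)
  expect_equal(fr$age_years[fr$caseid == "C0000001"], 54)
  expect_equal(fr$wt_kg[fr$caseid == "C0000003"], 120)
  # unit conversion
  expect_equal(faersdp:::normalize_age(c("24", "6"), c("MON", "DEC")),
               c(2, 60))
  expect_equal(faersdp:::normalize_weight("220", "LBS"), 99.79, tolerance = 1e-3)
  # unknown unit -> missing
  expect_true(is.na(faersdp:::normalize_age("50", "XX")))
})
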