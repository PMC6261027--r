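make_clean_records <- function(df) {
  filter_noise(read_diagnostic_records(write_records_csv(df)))$records
}

test_that("case selection censors at the first target diagnosis", {
  # hand-applied rule on a 5-record fixture: P1 has target diagnoses on
  # 2001-03-01 and 2002-05-01; only pre-censor, non-target records stay
  df <- data.frame(
    patient_id = rep(pid(1), 5),
    visit_date = c("2000-05-01", "2001-02-28", "2001-03-01",
                   "2001-06-01", "2002-05-01"),
    code = c("250.00", "401.1", "714.0", "272.0", "714.0")
  )
  recs <- make_clean_records(df)
  cases <- select_cases(recs, registry = pid(1), target_code = "71400",
                        min_dx = 2)
  expect_length(cases, 1L)
  h <- cases[[pid(1)]]
  expect_equal(h$censor_date, as.Date("2001-03-01"))
  expect_equal(h$records$code5, c("25000", "40110"))
  expect_true(all(h$records$visit_date < h$censor_date))

  # registry conjunct: same diagnoses, not in registry -> not a case
  expect_warning(
    none <- select_cases(recs, registry = character(),
                         target_code = "71400", min_dx = 2),
    "empty registry")
  expect_length(none, 0L)
  # count threshold: one target diagnosis is not enough
  one <- make_clean_records(df[1:3, ])
  expect_length(select_cases(one, registry = pid(1),
                             target_code = "71400", min_dx = 2), 0L)
})

test_that("case selection is invariant to record order", {
  df <- data.frame(
    patient_id = rep(pid(1), 5),
    visit_date = c("2000-05-01", "2001-02-28", "2001-03-01",
                   "2001-06-01", "2002-05-01"),
    code = c("250.00", "401.1", "714.0", "272.0", "714.0")
  )
  recs <- make_clean_records(df)
  shuf <- recs[c(4, 1, 5, 3, 2), ]
  a <- select_cases(recs, pid(1), "71400", 2)
  b <- select_cases(shuf, pid(1), "71400", 2)
  expect_equal(a[[1]]$records$code5, b[[1]]$records$code5)
  expect_equal(a[[1]]$censor_date, b[[1]]$censor_date)
})

test_that("controls exclude all target-code evidence", {
  df <- data.frame(
    patient_id = c(rep(pid(1), 3), rep(pid(2), 3), pid(3), pid(3)),
    visit_date = c("2001-01-01", "2001-02-01", "2001-03-01",
                   "2002-01-01", "2002-02-01", "2002-03-01",
                   "2003-01-01", "2003-02-01"),
    code = c("250.00", "401.1", "272.0",      # P1: clean control
             "250.00", "714.0", "401.1",      # P2: sub-threshold target
             "714.0", "714.0")                # P3: case-grade evidence
  )
  recs <- make_clean_records(df)
  cases <- select_cases(recs, registry = pid(3), target_code = "71400",
                        min_dx = 2)
  ctrls <- select_controls(recs, names(cases), "71400")
  expect_equal(names(ctrls), pid(1))
  # sub-threshold target evidence: excluded from BOTH arms
  expect_false(pid(2) %in% c(names(cases), names(ctrls)))
  # control histories never contain the target code
  expect_false(any(vapply(ctrls, function(h) "71400" %in% h$records$code5,
                          logical(1))))
})

test_that("cohort invariants hold on a synthetic cohort", {
  cfg <- synth_config(n_cases = 15, n_controls = 25, vocab_size = 80,
                      k_themes = 3, noise_rate = 0.02, seed = 99)
  out <- generate_synthetic_emr(cfg, tempfile("emr"))
  recs <- filter_noise(read_diagnostic_records(out$records))$records
  coh <- build_cohort(recs, read_registry(out$registry), "71400")

  expect_length(intersect(names(coh$cases), names(coh$controls)), 0L)
  expect_setequal(names(coh$cases),
                  out$patient_ids[out$truth$labels == "case"])
  for (h in coh$cases) {
    expect_false("71400" %in% h$records$code5)
    expect_true(all(h$records$visit_date < h$censor_date))
  }
  for (h in coh$controls) expect_false("71400" %in% h$records$code5)
  # selection log counts are consistent
  expect_equal(coh$selection_log$cases + coh$selection_log$controls +
                 coh$selection_log$excluded_subthreshold_target,
               coh$selection_log$patients_with_records)
})

test_that("cohort summary reports prevalence and between-arm statistics", {
  # printed-count check: 1007 cases / 921192 controls rounds to 0.1%
  expect_equal(round(cohort_prevalence(1007, 921192), 1), 0.1)

  cfg <- synth_config(n_cases = 10, n_controls = 30, vocab_size = 60,
                      k_themes = 3, noise_rate = 0, seed = 7)
  out <- generate_synthetic_emr(cfg, tempfile("emr"))
  recs <- filter_noise(read_diagnostic_records(out$records))$records
  coh <- build_cohort(recs, read_registry(out$registry), "71400")
  sex <- setNames(rep(c("F", "M"), 20), out$patient_ids)
  s <- summarize_cohort(coh, sex = sex)
  expect_equal(s$prevalence_pct, 25)
  expect_true(all(c("records_per_year", "visits_per_year",
                    "distinct_codes") %in% s$continuous$variable))
  expect_true(all(is.finite(s$continuous$t)))
  expect_true(is.finite(s$proportions$chisq))

  # identical per-patient statistics on both arms give t = 0
  h1 <- make_history(pid(1), "case", c("25000", "40110"))
  h2 <- make_history(pid(2), "case", c("25000", "40110"))
  h3 <- make_history(pid(3), "control", c("25000", "40110"))
  h4 <- make_history(pid(4), "control", c("25000", "40110"))
  coh0 <- structure(list(cases = list(h1, h2), controls = list(h3, h4),
                         target_code = "71400",
                         window = as.Date(c("2000-01-01", "2008-12-31")),
                         selection_log = list()),
                    class = "risk_cohort")
  s0 <- summarize_cohort(coh0)
  expect_equal(s0$continuous$t, rep(0, 3))

  # balanced 2x2 sex table gives chi-squared 0
  names(coh0$cases) <- pid(1:2); names(coh0$controls) <- pid(3:4)
  sex0 <- setNames(c("F", "M", "F", "M"), pid(1:4))
  expect_equal(summarize_cohort(coh0, sex = sex0)$proportions$chisq, 0)
})
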