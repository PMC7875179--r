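test_that("cohort generation is deterministic for a fixed seed", {
  cc <- cohort_config(n_patients = 250)
  a <- generate_cohort(cc, seed = 77)
  b <- generate_cohort(cc, seed = 77)
  expect_identical(a, b)
  c2 <- generate_cohort(cc, seed = 78)
  expect_false(identical(a, c2))
})

test_that("category frequencies match the intake-stream calibration at full size", {
  cc <- cohort_config(n_patients = 3722)
  cohort <- generate_cohort(cc, seed = 2018, outcomes = FALSE)
  # each category count within the exact binomial 99% interval of its
  # target proportion
  check_freq <- function(observed_counts, probs) {
    for (lv in names(probs)) {
      if (probs[[lv]] == 0) {
        expect_identical(unname(observed_counts[lv] %||% 0L), 0L)
        next
      }
      k <- sum(observed_counts[lv], na.rm = TRUE)
      lo <- qbinom(0.005, 3722, probs[[lv]])
      hi <- qbinom(0.995, 3722, probs[[lv]])
      expect_gte(k, lo)
      expect_lte(k, hi)
    }
  }
  `%||%` <- function(a, b) if (is.na(a)) b else a
  check_freq(table(cohort$gender), cc$gender_freq)
  check_freq(table(cohort$ethnicity), cc$ethnicity_freq)
  check_freq(table(cohort$index_diagnosis), cc$diagnosis_freq)
  # age distribution: truncated at the eligibility minimum; closed-form
  # truncated-normal mean mu + sd * phi(a) / (1 - Phi(a))
  expect_true(all(cohort$age_at_index >= 14))
  a <- (14 - 37.5) / 18.4
  mu_trunc <- 37.5 + 18.4 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(cohort$age_at_index) - mu_trunc), 1)
  # entry dates inside the window
  expect_true(all(cohort$index_date >= cc$entry_start &
                    cohort$index_date <= cc$entry_end))
})

test_that("missingness schedule: zero fraction means complete at entry", {
  cc0 <- cohort_config(n_patients = 120, missing_frac = 0)
  cohort <- generate_cohort(cc0, seed = 5, outcomes = FALSE)
  expect_true(all(cohort$avail_week_ethnicity == 0))
  expect_true(all(cohort$avail_week_diagnosis == 0))
  cc1 <- cohort_config(n_patients = 2000, missing_frac = 0.35)
  cohort1 <- generate_cohort(cc1, seed = 6, outcomes = FALSE)
  late <- cohort1$avail_week_ethnicity > 0 | cohort1$avail_week_diagnosis > 0
  expect_equal(mean(late), 0.35, tolerance = 0.04)
  # age and gender are always present at entry
  expect_true(all(cohort1$avail_week_age == 0))
  expect_true(all(cohort1$avail_week_gender == 0))
})

test_that("a zero baseline hazard produces no events", {
  cc <- cohort_config(n_patients = 150,
                      baseline = baseline_survival("exponential", rate = 0))
  cohort <- generate_cohort(cc, seed = 9)
  expect_true(all(is.na(cohort$event_day)))
  expect_true(all(cohort$censor_day > 0))
})

test_that("reference-subject event times follow the exponential baseline law", {
  rate <- 1 / 500
  cc <- cohort_config(n_patients = 150, attrition_rate = 0,
                      followup_max_days = 100000,
                      baseline = baseline_survival("exponential",
                                                   rate = rate))
  model <- risk_model(cc$true_betas, cc$baseline)
  n <- 20000
  ref <- make_record("Z", age = 0)[rep(1, n), ]
  ref$patient_id <- sprintf("Z%05d", seq_len(n))
  out <- sample_event_times(ref, model, cc, seed = 123)
  fu <- observed_followup(out)
  expect_equal(mean(fu$event), 1)            # no censoring configured
  cv <- km_curve(fu$time, fu$event)
  # sup-norm distance to exp(-rate * t); day-rounding contributes < rate
  theo <- exp(-rate * cv$times)
  expect_lt(max(abs(cv$survival - theo)), 0.01)
  # doubling the hazard halves the median event time
  cc2 <- cohort_config(n_patients = 150, attrition_rate = 0,
                       followup_max_days = 100000,
                       baseline = baseline_survival("exponential",
                                                    rate = 2 * rate))
  out2 <- sample_event_times(ref, risk_model(cc2$true_betas, cc2$baseline),
                             cc2, seed = 123)
  m1 <- median(observed_followup(out)$time)
  m2 <- median(observed_followup(out2)$time)
  expect_equal(m1 / m2, 2, tolerance = 0.05)
  expect_equal(m1, log(2) / rate, tolerance = 0.05)
})

test_that("generator baseline calibration hits the target six-month proportion", {
  cc <- cohort_config(n_patients = 30000)
  expect_equal(
    psyriskscreen:::expected_event_proportion(cc$baseline$rate, cc, 183),
    38 / 3640, tolerance = 1e-6
  )
  cohort <- generate_cohort(cc, seed = 140)
  fu <- observed_followup(cohort)
  sim <- mean(fu$event == 1 & fu$time <= 183)
  expect_equal(sim, 38 / 3640, tolerance = 0.25)  # sampling noise at ~1%
})

test_that("the reference funnel fixture is hard-coded and reproduces every count", {
  fx <- make_reference_funnel_fixture()
  expect_identical(fx, make_reference_funnel_fixture())  # seed-independent
  f <- funnel_summary(fx$cases)
  expect_identical(f$detected, 117L)
  expect_identical(f$no_contact, 2L)
  expect_identical(f$prompted, 115L)
  expect_identical(f$responded, 89L)
  expect_identical(f$excluded, 18L)
  expect_identical(f$decisions, 71L)
  expect_identical(f$referred, 39L)
  expect_identical(unname(f$channels), c(33L, 20L, 6L, 30L))
  expect_identical(personalization_table(fx$cases),
                   matrix(c(44L, 31L, 15L, 25L), 2, byrow = TRUE,
                          dimnames = dimnames(personalization_table(fx$cases))))
  expect_identical(outreach_table(fx$cases),
                   matrix(c(29L, 5L, 60L, 21L), 2, byrow = TRUE,
                          dimnames = dimnames(outreach_table(fx$cases))))
  # the shipped CSV pair equals the in-code fixture
  csv <- read.csv(system.file("extdata", "reference_funnel_cases.csv",
                              package = "psyriskscreen"),
                  stringsAsFactors = FALSE)
  expect_identical(csv$state, fx$cases$state)
  expect_identical(csv$response_channel, fx$cases$response_channel)
  strata <- read.csv(system.file("extdata", "reference_followup_strata.csv",
                                 package = "psyriskscreen"),
                     stringsAsFactors = FALSE)
  expect_identical(strata$followed, fx$followup$followed)
  expect_identical(strata$events_6mo, fx$followup$events_6mo)
})

test_that("Cox fits on generated cohorts recover the generating betas without bias", {
  # parameter-recovery loop closure: mean bias across replicates is small
  # relative to the attainable Monte Carlo precision per coefficient
  dxf <- psyriskscreen:::screened_diagnosis_counts
  dxf["ARMS"] <- 0.02 * sum(dxf)
  cc <- cohort_config(n_patients = 30000, diagnosis_freq = dxf,
                      followup_max_days = 730)
  R <- 10
  est <- se <- matrix(NA_real_, R, length(table2_truth),
                      dimnames = list(NULL, names(table2_truth)))
  for (r in seq_len(R)) {
    cohort <- generate_cohort(cc, seed = 5000 + r)
    fu <- observed_followup(cohort)
    fit <- fit_cox_pl(
      cohort[, c("age_at_index", "gender", "ethnicity", "index_diagnosis")],
      fu$time, fu$event
    )
    est[r, names(fit$coefficients)] <- fit$coefficients
    se[r, names(fit$se)] <- fit$se
  }
  bias <- colMeans(est) - table2_truth
  tol <- pmax(0.05, 3 * colMeans(se) / sqrt(R))
  expect_true(all(abs(bias) < tol))
  # the precisely-estimated coefficients meet the strict 0.05 band outright
  tight <- names(which(colMeans(se) < 0.1))
  expect_gte(length(tight), 3)
  expect_true(all(abs(bias[tight]) < 0.05))
})

test_that("simulated personalization and outreach odds ratios stay in the sanity envelope", {
  cc <- cohort_config(n_patients = 600)
  cohort <- generate_cohort(cc, seed = 310)
  model <- risk_model(cc$true_betas, cc$baseline)
  det <- run_weekly_screening(cohort, model)$detections
  expect_gt(nrow(det), 50)
  R <- 200
  or_p <- or_o <- numeric(R)
  for (r in seq_len(R)) {
    cases <- run_alert_workflow(open_case(det, cohort), cc$behaviour,
                                seed = 9000 + r)
    or_p[r] <- fisher_exact_2x2(personalization_table(cases))$estimate
    or_o[r] <- fisher_exact_2x2(outreach_table(cases))$estimate
  }
  expect_gt(median(or_p, na.rm = TRUE), 1.5)
  expect_lt(median(or_p, na.rm = TRUE), 3.5)
  expect_gt(median(or_o, na.rm = TRUE), 1.0)
  expect_lt(median(or_o, na.rm = TRUE), 3.5)
})
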