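test_that("eligibility rules name the first failing criterion", {
  cfg <- study_config()
  records <- rbind(
    make_record("A", age = 13),                       # too young
    make_record("B", diagnosis = "Organic"),          # organic class
    make_record("C", diagnosis = "Psychotic"),        # already psychotic
    make_record("D", patient_contact = FALSE),        # no contact details
    make_record("E", index_date = "2017-01-01"),      # before the window
    make_record("F", age = 14),                       # boundary: eligible
    make_record("G", diagnosis = "ARMS")              # CHR-P designation
  )
  expect_identical(check_eligibility(records, cfg),
                   c("age", "diagnosis", "diagnosis", "contact", "window",
                     "eligible", "eligible"))
})

test_that("screening waits for late predictors and applies the threshold inclusively", {
  cfg <- study_config()
  model <- default_risk_model()
  rec <- make_record("P1", avail = c(0, 0, 3, 0))
  expect_identical(screen_patient(rec, 0, model, cfg)$status,
                   "AWAITING_PREDICTORS")
  expect_identical(screen_patient(rec, 3, model, cfg)$status, "SCREENED")

  # exact-boundary detection: S0(730) = 0.95 puts the reference subject
  # at risk exactly 0.05
  m_at <- risk_model(risk_coefficients(), baseline_survival(
    "step", steps = data.frame(time = 730, survival = 0.95)
  ))
  rec0 <- make_record("P2", age = 0, diagnosis = "ARMS")
  out <- screen_patient(rec0, 0, m_at, cfg)
  expect_equal(out$risk, 0.05)
  expect_true(out$detected)
  m_below <- risk_model(risk_coefficients(), baseline_survival(
    "step", steps = data.frame(time = 730, survival = 0.951)
  ))
  expect_false(screen_patient(rec0, 0, m_below, cfg)$detected)
})

test_that("the weekly loop screens patients at their completion week", {
  cfg <- study_config()
  model <- default_risk_model()
  # 10 patients entering at week 0; three complete only at week 2
  avail <- c(rep(0, 7), rep(2, 3))
  cohort <- do.call(rbind, lapply(1:10, function(i) {
    make_record(sprintf("W%02d", i), index_date = "2018-05-14",
                avail = c(0, 0, avail[i], 0))
  }))
  res <- run_weekly_screening(cohort, model, cfg)
  expect_identical(res$log$status, rep("SCREENED", 10))
  expect_identical(res$log$week, as.integer(c(rep(0, 7), rep(2, 3))))
})

test_that("patients whose predictors never arrive are never risk-scored", {
  cfg <- study_config()
  model <- default_risk_model()
  cohort <- rbind(
    make_record("N1", avail = c(0, 0, NA, 0)),        # ethnicity never
    make_record("N2")
  )
  res <- run_weekly_screening(cohort, model, cfg)
  expect_identical(res$log$status[1], "AWAITING_PREDICTORS")
  expect_true(is.na(res$log$risk[1]))
  expect_identical(res$log$status[2], "SCREENED")
})

test_that("every eligible patient ends in exactly one terminal state and counts conserve", {
  cfg <- study_config()
  model <- default_risk_model()
  cc <- cohort_config(n_patients = 400, p_patient_contact = 0.9)
  cohort <- generate_cohort(cc, seed = 17)
  res <- run_weekly_screening(cohort, model, cfg)
  expect_identical(nrow(res$log), nrow(cohort))
  st <- res$log$status
  n_inel <- sum(grepl("^INELIGIBLE", st))
  n_await <- sum(st == "AWAITING_PREDICTORS")
  n_screen <- sum(st == "SCREENED")
  expect_identical(n_inel + n_await + n_screen, nrow(cohort))
  # detections imply screened status and risk at or above threshold
  expect_true(all(res$detections$status == "SCREENED"))
  expect_true(all(res$detections$risk >= cfg$threshold))
})

test_that("lowering the threshold never removes a detection", {
  model <- default_risk_model()
  cohort <- generate_cohort(cohort_config(n_patients = 300), seed = 23)
  det_5 <- run_weekly_screening(cohort, model,
                                study_config(threshold = 0.05))$detections
  det_2 <- run_weekly_screening(cohort, model,
                                study_config(threshold = 0.02))$detections
  expect_true(all(det_5$patient_id %in% det_2$patient_id))
})

test_that("screening is independent of patient order and of missingness when absent", {
  cfg <- study_config()
  model <- default_risk_model()
  cohort <- generate_cohort(cohort_config(n_patients = 200), seed = 31)
  res <- run_weekly_screening(cohort, model, cfg)
  perm <- sample(nrow(cohort))
  res_p <- run_weekly_screening(cohort[perm, ], model, cfg)
  reordered <- res_p$log[match(res$log$patient_id, res_p$log$patient_id), ]
  rownames(reordered) <- NULL
  expect_equal(reordered, res$log)

  # zero missingness: screening week equals entry week for everyone
  cc0 <- cohort_config(n_patients = 150, missing_frac = 0)
  coh0 <- generate_cohort(cc0, seed = 32)
  expect_true(all(coh0$avail_week_ethnicity == 0) &&
                all(coh0$avail_week_diagnosis == 0))
  res0 <- run_weekly_screening(coh0, model, cfg)
  entry <- floor(as.numeric(as.Date(coh0$index_date) - cfg$start_date) / 7)
  expect_identical(res0$log$week, as.integer(entry))
})

test_that("the diagnostic-lag filter removes only observed early converters", {
  cohort <- rbind(
    make_record("L1", event_day = 45, censor_day = 45),    # early converter
    make_record("L2", event_day = 120, censor_day = 120),  # late converter
    make_record("L3", event_day = NA, censor_day = 30)     # early censoring
  )
  kept <- apply_diagnostic_lag_filter(cohort, lag_days = 90)
  expect_identical(kept$patient_id, c("L2", "L3"))
  # oracle: recount over all patients
  expect_identical(
    sort(kept$patient_id),
    sort(cohort$patient_id[!(!is.na(cohort$event_day) &
                               cohort$event_day < 90)])
  )
  expect_error(apply_diagnostic_lag_filter(cohort, lag_days = -1),
               "non-negative")
})

test_that("cohort CSV round-trips including missing availability weeks", {
  cohort <- generate_cohort(cohort_config(n_patients = 40), seed = 3)
  cohort$avail_week_ethnicity[1] <- Inf
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_true(is.na(back$avail_week_ethnicity[1]))
  back$avail_week_ethnicity[1] <- Inf
  expect_equal(back$age_at_index, cohort$age_at_index)
  expect_identical(back$index_diagnosis, cohort$index_diagnosis)
  expect_identical(back$patient_contact, cohort$patient_contact)
  expect_identical(as.Date(back$index_date), as.Date(cohort$index_date))
})
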