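wf_certain <- function(p) {
  workflow_config(response_prob = c(email1 = p, email2 = p,
                                    email3 = p, phone = p),
                  personalization_effect = 1, outreach_effect = 1)
}

test_that("cases open in NO_CONTACT or EMAIL1_SENT according to clinician contact", {
  cohort <- rbind(
    make_record("C1", clinician_contact = "absent"),
    make_record("C2", clinician_contact = "valid"),
    make_record("C3", clinician_contact = "incorrect")
  )
  det <- data.frame(patient_id = c("C1", "C2", "C3"), week = c(4L, 4L, 6L))
  cases <- open_case(det, cohort)
  expect_identical(cases$state, c("NO_CONTACT", "EMAIL1_SENT", "EMAIL1_SENT"))
  expect_identical(cases$response_channel, rep("NONE", 3))
  expect_identical(cases$detection_week, c(4L, 4L, 6L))
  # the fixture's contact split: 117 detections, 2 absent -> 115 prompts
  fx <- make_reference_funnel_fixture()
  expect_identical(sum(fx$cases$state != "NO_CONTACT"), 115L)
})

test_that("a certain response closes the case at email1 in the same week", {
  cohort <- make_record("C2")
  cases <- open_case(data.frame(patient_id = "C2", week = 2L), cohort)
  done <- advance_case(cases, wf_certain(1), current_week = 2L,
                       response_draw = 0)
  expect_identical(done$state, "RESPONDED")
  expect_identical(done$response_channel, "EMAIL1")
  expect_identical(done$response_week, 2L)
})

test_that("no response anywhere traverses all four stages then closes NO_RESPONSE", {
  cohort <- make_record("C2")
  case <- open_case(data.frame(patient_id = "C2", week = 0L), cohort)
  cfg <- wf_certain(0)
  traversed <- character()
  week <- 0L
  for (k in 1:4) {
    traversed <- c(traversed, case$state)
    case <- advance_case(case, cfg, week, response_draw = 0.99)
    week <- week + cfg$step_gap_weeks
  }
  expect_identical(traversed, c("EMAIL1_SENT", "EMAIL2_SENT", "EMAIL3_SENT",
                                "PHONE_STAGE"))
  expect_identical(case$state, "NO_RESPONSE")
  expect_error(advance_case(case, cfg, week, 0), "terminal")
})

test_that("a phone-only responder answers three step-gaps after detection", {
  cohort <- make_record("C2")
  cfg <- workflow_config(response_prob = c(email1 = 0, email2 = 0,
                                           email3 = 0, phone = 1),
                         personalization_effect = 1, outreach_effect = 1)
  case <- open_case(data.frame(patient_id = "C2", week = 5L), cohort)
  case$personalization <- "trust_id"
  done <- run_alert_workflow(case, cfg, seed = 9)
  expect_identical(done$state, "RESPONDED")
  expect_identical(done$response_channel, "PHONE")
  expect_equal(done$response_week, 5 + 3 * cfg$step_gap_weeks)
})

test_that("resolution assigns exclusions before referral and rejects bad states", {
  cohort <- make_record("C2")
  case <- open_case(data.frame(patient_id = "C2", week = 0L), cohort)
  expect_error(resolve_case(case, workflow_config(), 0.5, 0.5),
               "not responded")
  case$state <- "RESPONDED"
  cfg <- workflow_config()
  excl <- resolve_case(case, cfg, exclusion_draw = 0, referral_draw = 0)
  expect_identical(excl$exclusion_reason, "moved_out")
  expect_true(is.na(excl$referral))
  kept <- resolve_case(case, cfg, exclusion_draw = 0.99, referral_draw = 0)
  expect_identical(kept$exclusion_reason, "none")
  expect_identical(kept$referral, "REFERRED")
  not_ref <- resolve_case(case, cfg, exclusion_draw = 0.99,
                          referral_draw = 0.99)
  expect_identical(not_ref$referral, "NOT_REFERRED")
  expect_identical(not_ref$nonreferral_reason, "acute_phase")
})

test_that("funnel counting matches a brute-force tally and conserves cases", {
  set.seed(88)
  cohort <- do.call(rbind, lapply(1:40, function(i) {
    make_record(sprintf("R%02d", i),
                clinician_contact = sample(c("valid", "incorrect", "absent"),
                                           1, prob = c(0.8, 0.1, 0.1)),
                borough = sample(c("Lambeth", "Croydon"), 1))
  }))
  det <- data.frame(patient_id = cohort$patient_id,
                    week = sample(0:20, 40, replace = TRUE))
  cases <- run_alert_workflow(open_case(det, cohort), workflow_config(),
                              seed = 5)
  f <- funnel_summary(cases)
  o <- oracle_funnel(cases)
  expect_identical(f$detected, unname(o["detected"]))
  expect_identical(f$no_contact, unname(o["no_contact"]))
  expect_identical(f$prompted, unname(o["prompted"]))
  expect_identical(f$responded, unname(o["responded"]))
  expect_identical(f$excluded, unname(o["excluded"]))
  expect_identical(f$decisions, unname(o["decisions"]))
  expect_identical(f$referred, unname(o["referred"]))
  # conservation identities
  expect_identical(f$prompted, f$detected - f$no_contact)
  expect_identical(f$decisions, f$responded - f$excluded)
  expect_identical(f$referred + f$not_referred, f$decisions)
  expect_identical(unname(sum(f$channels)), f$responded)
  # order invariance
  f2 <- funnel_summary(cases[sample(nrow(cases)), ])
  expect_identical(unclass(f), unclass(f2))
  # empty case list
  f0 <- funnel_summary(cases[0, ])
  expect_identical(f0$detected, 0L)
  expect_identical(unname(sum(f0$channels)), 0L)
})

test_that("certain response everywhere gives full adherence through EMAIL1", {
  cohort <- do.call(rbind, lapply(1:25, function(i) {
    make_record(sprintf("A%02d", i))
  }))
  det <- data.frame(patient_id = cohort$patient_id, week = 0L)
  cases <- run_alert_workflow(open_case(det, cohort), wf_certain(1),
                              seed = 2)
  expect_equal(adherence_proportion(cases), 1)
  expect_true(all(cases$response_channel == "EMAIL1"))
  # response weeks never decrease along the escalation order
  cases2 <- run_alert_workflow(open_case(det, cohort), workflow_config(),
                               seed = 3)
  rw <- cases2$response_week
  ch <- match(cases2$response_channel, c("EMAIL1", "EMAIL2", "EMAIL3",
                                         "PHONE"))
  ok <- !is.na(rw)
  expect_true(all(rw[ok] == cases2$detection_week[ok] + (ch[ok] - 1L)))
})

test_that("case log CSV round-trips", {
  fx <- make_reference_funnel_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_case_log(fx$cases, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 117L)
  expect_identical(sum(back$state == "RESPONDED"), 89L)
})
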