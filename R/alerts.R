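alert_channels <- c("EMAIL1", "EMAIL2", "EMAIL3", "PHONE")
stage_states <- c("EMAIL1_SENT", "EMAIL2_SENT", "EMAIL3_SENT", "PHONE_STAGE")
exclusion_reasons <- c("none", "moved_out", "organic_condition", "language",
                       "psychosis_from_collateral", "declined", "other")

#' Configuration of the clinician alert-escalation workflow
#'
#' Each detection opens an alert case that escalates through four sequential
#' contact stages — first email, reminder email, third email to an alternate
#' contact (care coordinator or GP when the responsible clinician's details
#' are incorrect), then phone — at `step_gap_weeks` intervals until the
#' clinician responds or the channels are exhausted.
#'
#' Personalization (patient name instead of Trust ID in the alert email)
#' and outreach (clinicians in the outreach borough, Lambeth, briefed
#' before deployment) act as multiplicative odds modifiers on every
#' channel's response probability. The default base probabilities (the
#' reference condition: Trust-ID alert, no outreach) and the two modifiers
#' are jointly calibrated, once and analytically, so that under the
#' deployed mix (65% named alerts, 30% outreach) the implied stage-wise
#' conditional response rates equal the observed 33/115, 20/82, 6/62 and
#' 30/56, and the implied aggregate odds ratios equal the published 2.35
#' (personalization, response by email) and 2.02 (outreach, response by any
#' channel). Per-channel modifiers smaller than the aggregate ORs are
#' expected: a multi-stage escalation amplifies a per-stage odds effect.
#'
#' @param step_gap_weeks weeks between escalation steps (default 1).
#' @param response_prob named base response probabilities per channel
#'   (`email1`, `email2`, `email3`, `phone`).
#' @param personalization_effect odds multiplier when the alert carries the
#'   patient's name rather than a Trust ID.
#' @param outreach_effect odds multiplier when outreach was conducted in the
#'   clinician's borough.
#' @param p_named probability that an alert is personalised with the
#'   patient's name (default 75/115, the deployed mix).
#' @param referral_prob probability that a responding, non-excluded case is
#'   referred for face-to-face assessment (default 39/71).
#' @param exclusion_probs named probabilities of each exclusion category for
#'   a responded case (remainder = not excluded); defaults total 18/89
#'   across the categories reported for the deployment.
#' @param acute_phase_frac fraction of non-referrals tagged with the
#'   predominant reason (patient in an acute symptomatic phase).
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(step_gap_weeks = 1,
                            response_prob = c(email1 = 0.1739,
                                              email2 = 0.1492,
                                              email3 = 0.0559,
                                              phone = 0.4101),
                            personalization_effect = 2.0547,
                            outreach_effect = 1.6217,
                            p_named = 75 / 115,
                            referral_prob = 39 / 71,
                            exclusion_probs = c(
                              moved_out = 0.1198, organic_condition = 0.0449,
                              language = 0.0225,
                              psychosis_from_collateral = 0.0075,
                              declined = 0.0075
                            ),
                            acute_phase_frac = 0.6) {
  stopifnot(
    step_gap_weeks >= 0,
    setequal(names(response_prob), c("email1", "email2", "email3", "phone")),
    all(response_prob >= 0 & response_prob <= 1),
    personalization_effect > 0, outreach_effect > 0,
    p_named >= 0, p_named <= 1,
    referral_prob >= 0, referral_prob <= 1,
    all(exclusion_probs >= 0), sum(exclusion_probs) <= 1,
    all(names(exclusion_probs) %in% setdiff(exclusion_reasons, "none")),
    acute_phase_frac >= 0, acute_phase_frac <= 1
  )
  structure(list(
    step_gap_weeks = step_gap_weeks,
    response_prob = response_prob[c("email1", "email2", "email3", "phone")],
    personalization_effect = personalization_effect,
    outreach_effect = outreach_effect,
    p_named = p_named,
    referral_prob = referral_prob,
    exclusion_probs = exclusion_probs,
    acute_phase_frac = acute_phase_frac
  ), class = "workflow_config")
}

## channel response probability after odds modification
modified_prob <- function(base, named, outreach, config) {
  if (base <= 0) return(0)
  if (base >= 1) return(1)
  odds <- base / (1 - base) *
    ifelse(named, config$personalization_effect, 1) *
    ifelse(outreach, config$outreach_effect, 1)
  odds / (1 + odds)
}

#' Open alert cases for detections
#'
#' One case per detection. Cases whose responsible clinician has no contact
#' details on the record enter (and stay in) `NO_CONTACT`: no prompt is ever
#' sent. All others enter `EMAIL1_SENT` at the detection week. Outreach is a
#' property of the clinician's borough (Lambeth).
#'
#' @param detections detection rows from [run_weekly_screening()]
#'   (`patient_id`, `week`).
#' @param cohort cohort data frame (for `clinician_contact` and `borough`).
#' @param personalization optional character vector (`"patient_name"` /
#'   `"trust_id"`) per detection; defaults to `NA`, to be assigned by the
#'   workflow driver.
#' @return Alert case data frame, one row per detection: `patient_id`,
#'   `state`, `detection_week`, `clinician_contact`, `response_channel`,
#'   `response_week`, `personalization`, `outreach`, `exclusion_reason`,
#'   `referral`, `nonreferral_reason`.
#' @export
open_case <- function(detections, cohort, personalization = NA_character_) {
  stopifnot(is.data.frame(detections), is.data.frame(cohort))
  i <- match(detections$patient_id, cohort$patient_id)
  if (anyNA(i)) stop("detections refer to unknown patients", call. = FALSE)
  contact <- cohort$clinician_contact[i]
  check_level(contact, c("valid", "incorrect", "absent"), "clinician_contact")
  data.frame(
    patient_id = detections$patient_id,
    state = ifelse(contact == "absent", "NO_CONTACT", "EMAIL1_SENT"),
    detection_week = detections$week,
    clinician_contact = contact,
    response_channel = "NONE",
    response_week = NA_integer_,
    personalization = personalization,
    outreach = cohort$borough[i] == "Lambeth",
    exclusion_reason = "none",
    referral = NA_character_,
    nonreferral_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Advance one alert case by one escalation step
#'
#' At the case's current stage a Bernoulli response draw (the channel's base
#' probability with personalization/outreach odds modifiers applied) either
#' closes the case as `RESPONDED`, recording the channel and week, or
#' escalates it along email1 -> email2 -> email3 -> phone. A case that
#' traverses all four stages without response becomes `NO_RESPONSE`. Cases
#' with incorrect clinician contact route the third email to the alternate
#' contact; the state-machine semantics are identical.
#'
#' @param case one-row alert case data frame (non-terminal state).
#' @param config a [workflow_config()].
#' @param current_week study week at which the step happens.
#' @param response_draw uniform draw in \[0, 1\); response occurs when it is
#'   below the modified channel probability.
#' @return The updated one-row case.
#' @export
advance_case <- function(case, config, current_week, response_draw) {
  stopifnot(is.data.frame(case), nrow(case) == 1L,
            inherits(config, "workflow_config"))
  k <- match(case$state, stage_states)
  if (is.na(k)) {
    stop("cannot advance a case in terminal state ", case$state,
         call. = FALSE)
  }
  p <- modified_prob(config$response_prob[[k]],
                     identical(case$personalization, "patient_name"),
                     isTRUE(case$outreach), config)
  if (response_draw < p) {
    case$state <- "RESPONDED"
    case$response_channel <- alert_channels[k]
    case$response_week <- as.integer(current_week)
  } else if (k < length(stage_states)) {
    case$state <- stage_states[k + 1L]
  } else {
    case$state <- "NO_RESPONSE"
  }
  case
}

#' Resolve a responded case: exclusion, then referral decision
#'
#' Exclusion is assessed first (patient moved out of the catchment area,
#' organic condition, language barrier, psychosis evident from collateral
#' information, declined, other); excluded cases receive no referral
#' decision (`referral = NA`). Surviving cases are referred with probability
#' `referral_prob`; non-referrals are tagged with a reason, predominantly
#' the patient being in an acute symptomatic phase.
#'
#' @param case one-row alert case in state `RESPONDED`.
#' @param config a [workflow_config()].
#' @param exclusion_draw uniform draw mapped onto the exclusion categories
#'   by their cumulative probabilities (values above the total mean no
#'   exclusion).
#' @param referral_draw uniform draw; referral when below `referral_prob`.
#' @return The updated one-row case.
#' @export
resolve_case <- function(case, config, exclusion_draw, referral_draw) {
  stopifnot(is.data.frame(case), nrow(case) == 1L,
            inherits(config, "workflow_config"))
  if (!identical(case$state, "RESPONDED")) {
    stop("cannot resolve a case that has not responded (state ",
         case$state, ")", call. = FALSE)
  }
  cum <- cumsum(config$exclusion_probs)
  hit <- which(exclusion_draw < cum)
  if (length(hit)) {
    case$exclusion_reason <- names(config$exclusion_probs)[hit[1L]]
    case$referral <- NA_character_
  } else {
    case$exclusion_reason <- "none"
    if (referral_draw < config$referral_prob) {
      case$referral <- "REFERRED"
    } else {
      case$referral <- "NOT_REFERRED"
      case$nonreferral_reason <- "acute_phase"
    }
  }
  case
}

#' Run the full alert workflow over a set of detections
#'
#' Vectorised driver of the escalation state machine: assigns
#' personalization, advances every open case through the four contact
#' stages at `step_gap_weeks` intervals, then resolves responded cases
#' (exclusion, referral, non-referral reason). Deterministic given the
#' seed.
#'
#' @param cases alert case data frame from [open_case()].
#' @param config a [workflow_config()].
#' @param seed integer seed for all draws.
#' @return The completed case data frame.
#' @export
run_alert_workflow <- function(cases, config = workflow_config(), seed = 1L) {
  stopifnot(is.data.frame(cases), inherits(config, "workflow_config"))
  seeds <- derive_seeds(seed, 3L)
  n <- nrow(cases)
  if (n == 0L) return(cases)

  set.seed(seeds[1])
  assign_pers <- is.na(cases$personalization)
  cases$personalization[assign_pers] <- ifelse(
    runif(sum(assign_pers)) < config$p_named, "patient_name", "trust_id"
  )

  set.seed(seeds[2])
  for (k in seq_along(stage_states)) {
    active <- which(cases$state == stage_states[k])
    if (!length(active)) next
    week <- cases$detection_week[active] + (k - 1L) * config$step_gap_weeks
    draws <- runif(length(active))
    for (j in seq_along(active)) {
      cases[active[j], ] <- advance_case(cases[active[j], , drop = FALSE],
                                         config, week[j], draws[j])
    }
  }

  set.seed(seeds[3])
  responded <- which(cases$state == "RESPONDED")
  if (length(responded)) {
    ex_draws <- runif(length(responded))
    ref_draws <- runif(length(responded))
    for (j in seq_along(responded)) {
      cases[responded[j], ] <- resolve_case(
        cases[responded[j], , drop = FALSE], config,
        ex_draws[j], ref_draws[j]
      )
    }
  }
  cases
}

#' Funnel summary of an alert case set
#'
#' Pure counting over the case partition: detections, cases without
#' clinician contact, prompts sent, responses, exclusions, referral
#' decisions, referrals — plus per-channel response counts. Conserves cases
#' at every stage: `prompted = detected - no_contact`,
#' `decisions = responded - excluded`,
#' `referred + not_referred = decisions`.
#'
#' @param cases alert case data frame (completed).
#' @return An object of class `funnel_summary`: a list of counts
#'   (`detected`, `no_contact`, `prompted`, `responded`, `excluded`,
#'   `decisions`, `referred`, `not_referred`, `no_response`) and a named
#'   vector `channels`.
#' @export
funnel_summary <- function(cases) {
  stopifnot(is.data.frame(cases))
  responded <- cases$state == "RESPONDED"
  excluded <- responded & cases$exclusion_reason != "none"
  channels <- vapply(alert_channels,
                     function(ch) sum(cases$response_channel == ch,
                                      na.rm = TRUE),
                     integer(1))
  structure(list(
    detected = nrow(cases),
    no_contact = sum(cases$state == "NO_CONTACT"),
    prompted = sum(cases$state != "NO_CONTACT"),
    responded = sum(responded),
    excluded = sum(excluded),
    decisions = sum(responded) - sum(excluded),
    referred = sum(cases$referral == "REFERRED", na.rm = TRUE),
    not_referred = sum(cases$referral == "NOT_REFERRED", na.rm = TRUE),
    no_response = sum(cases$state == "NO_RESPONSE"),
    channels = channels
  ), class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat("Alert funnel\n")
  cat(sprintf("  detected   %5d\n  no contact %5d\n  prompted   %5d\n",
              x$detected, x$no_contact, x$prompted))
  cat(sprintf("  responded  %5d  (EMAIL1 %d, EMAIL2 %d, EMAIL3 %d, PHONE %d)\n",
              x$responded, x$channels[["EMAIL1"]], x$channels[["EMAIL2"]],
              x$channels[["EMAIL3"]], x$channels[["PHONE"]]))
  cat(sprintf("  excluded   %5d\n  decisions  %5d\n  referred   %5d\n",
              x$excluded, x$decisions, x$referred))
  invisible(x)
}

#' Write the alert case log CSV
#'
#' Columns `patient_id, state, response_channel, response_week,
#' personalization, outreach, exclusion_reason, referral,
#' nonreferral_reason`.
#'
#' @param cases alert case data frame.
#' @param path file path.
#' @export
write_case_log <- function(cases, path) {
  cols <- c("patient_id", "state", "response_channel", "response_week",
            "personalization", "outreach", "exclusion_reason", "referral",
            "nonreferral_reason")
  write.csv(cases[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
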