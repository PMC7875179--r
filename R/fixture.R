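#' Deterministic reference funnel fixture
#'
#' A hard-coded, seed-independent set of 117 alert cases whose funnel
#' exactly matches the outcome funnel of the original deployment of the
#' calculator: 2 cases without clinician contact, 115 prompts, 89 responses
#' distributed over the channels as (33, 20, 6, 30), 18 post-response
#' exclusions, 71 referral decisions and 39 referrals. The personalization
#' margin reproduces the published email-response comparison (44/75 named
#' vs 15/40 Trust-ID; the published 2x2 counts responders *by email*, which
#' is why 44 + 15 equals the 59 email responses and not the 89 total
#' responses) and the outreach margin the any-channel comparison
#' (29/34 vs 60/81).
#'
#' The exclusion breakdown across categories (10, 4, 2, 1, 1) is synthetic
#' — only the total of 18 was published for the post-response stage — as is
#' the joint personalization-by-outreach layout; all published margins are
#' exact. Follow-up strata counts accompany the cases: 3640 of 3722
#' screened patients followed to six months with 38 psychosis transitions,
#' 101 of 115 detected with 9 transitions, and 49 detected-but-not-referred
#' followed with 3 transitions.
#'
#' @return A list of class `funnel_fixture`: `cases` (alert case data
#'   frame, 117 rows) and `followup` (data frame `stratum`, `n`,
#'   `followed`, `events_6mo`).
#' @export
make_reference_funnel_fixture <- function() {
  ## per-channel layout: count, named among them, outreach among them
  layout <- data.frame(
    channel = c("EMAIL1", "EMAIL2", "EMAIL3", "PHONE", "NONE"),
    state = c(rep("RESPONDED", 4), "NO_RESPONSE"),
    n = c(33L, 20L, 6L, 30L, 26L),
    named = c(24L, 15L, 5L, 20L, 11L),
    outreach = c(11L, 6L, 2L, 10L, 5L),
    week = c(0L, 1L, 2L, 3L, NA_integer_),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    l <- layout[i, ]
    data.frame(
      state = rep(l$state, l$n),
      response_channel = rep(l$channel, l$n),
      response_week = rep(l$week, l$n),
      personalization = rep(c("patient_name", "trust_id"),
                            c(l$named, l$n - l$named)),
      outreach = seq_len(l$n) <= l$outreach,
      stringsAsFactors = FALSE
    )
  })
  prompted <- do.call(rbind, rows)
  no_contact <- data.frame(
    state = rep("NO_CONTACT", 2), response_channel = "NONE",
    response_week = NA_integer_, personalization = NA_character_,
    outreach = FALSE, stringsAsFactors = FALSE
  )
  cases <- rbind(no_contact, prompted)
  cases <- data.frame(
    patient_id = sprintf("D%03d", seq_len(nrow(cases))),
    state = cases$state,
    detection_week = 0L,
    clinician_contact = ifelse(cases$state == "NO_CONTACT", "absent",
                               "valid"),
    response_channel = cases$response_channel,
    response_week = cases$response_week,
    personalization = cases$personalization,
    outreach = cases$outreach,
    exclusion_reason = "none",
    referral = NA_character_,
    nonreferral_reason = NA_character_,
    stringsAsFactors = FALSE
  )

  responded <- which(cases$state == "RESPONDED")
  excl <- rep(c("moved_out", "organic_condition", "language",
                "psychosis_from_collateral", "declined"),
              c(10L, 4L, 2L, 1L, 1L))
  cases$exclusion_reason[responded[seq_along(excl)]] <- excl
  deciders <- responded[-seq_along(excl)]             # 71 decisions
  cases$referral[deciders[1:39]] <- "REFERRED"
  cases$referral[deciders[40:71]] <- "NOT_REFERRED"
  cases$nonreferral_reason[deciders[40:59]] <- "acute_phase"
  cases$nonreferral_reason[deciders[60:71]] <- "other"

  followup <- data.frame(
    stratum = c("screened", "detected", "detected_not_referred"),
    n = c(3722L, 115L, NA_integer_),
    followed = c(3640L, 101L, 49L),
    events_6mo = c(38L, 9L, 3L),
    stringsAsFactors = FALSE
  )
  structure(list(cases = cases, followup = followup),
            class = "funnel_fixture")
}

#' 2x2 response tables from an alert case set
#'
#' `personalization_table()` cross-tabulates personalization (patient name
#' vs Trust ID) against response *by email* (channels EMAIL1-3) among
#' prompted cases — the comparison as published. `outreach_table()`
#' cross-tabulates outreach against response by any channel among prompted
#' cases.
#'
#' @param cases completed alert case data frame.
#' @return 2x2 integer matrix (rows: exposed/unexposed, columns:
#'   responded/not).
#' @export
personalization_table <- function(cases) {
  p <- cases[cases$state != "NO_CONTACT", ]
  email <- p$response_channel %in% c("EMAIL1", "EMAIL2", "EMAIL3")
  named <- p$personalization == "patient_name"
  matrix(c(sum(named & email), sum(named & !email),
           sum(!named & email), sum(!named & !email)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("patient_name", "trust_id"),
                         c("responded_email", "not")))
}

#' @rdname personalization_table
#' @export
outreach_table <- function(cases) {
  p <- cases[cases$state != "NO_CONTACT", ]
  resp <- p$state == "RESPONDED"
  matrix(c(sum(p$outreach & resp), sum(p$outreach & !resp),
           sum(!p$outreach & resp), sum(!p$outreach & !resp)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("outreach", "no_outreach"),
                         c("responded", "not")))
}
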