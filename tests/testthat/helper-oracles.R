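## Independent brute-force oracles used to cross-check the implementation.
## These deliberately use the most literal formulation available (explicit
## nested loops, direct products over risk sets, dense grid search) and
## share no code with the package internals.

## Harrell's C by explicit double loop over all ordered pairs.
oracle_concordance <- function(times, events, scores) {
  n <- length(times)
  num <- den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (times[i] < times[j] && events[i] == 1) ||
        (times[i] == times[j] && events[i] == 1 && events[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

## Kaplan-Meier product over risk sets, with Greenwood variance, events
## before censorings at tied times.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  gsum <- 0
  out <- data.frame(time = ut, n_risk = NA_real_, n_event = NA_real_,
                    survival = NA_real_, var = NA_real_)
  for (k in seq_along(ut)) {
    t <- ut[k]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    gsum <- if (n_risk > d) gsum + d / (n_risk * (n_risk - d)) else Inf
    out$n_risk[k] <- n_risk
    out$n_event[k] <- d
    out$survival[k] <- s
    out$var[k] <- if (s > 0) s^2 * gsum else 0
  }
  out
}

## Two-group log-rank chi-square from the O-E / V tables, by hand.
oracle_logrank <- function(timesA, eventsA, timesB, eventsB) {
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c(0, 1), c(length(timesA), length(timesB)))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- v <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

## Cox partial log-likelihood for a single binary covariate, untied times.
oracle_cox_pl <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

## Funnel tally by direct recount over the case rows.
oracle_funnel <- function(cases) {
  responded <- sum(cases$state == "RESPONDED")
  excluded <- sum(cases$state == "RESPONDED" &
                    cases$exclusion_reason != "none")
  c(detected = nrow(cases),
    no_contact = sum(cases$state == "NO_CONTACT"),
    prompted = sum(cases$state != "NO_CONTACT"),
    responded = responded,
    excluded = excluded,
    decisions = responded - excluded,
    referred = sum(!is.na(cases$referral) & cases$referral == "REFERRED"))
}

## Closed-form population response probability of the escalation machine:
## per stratum (named x outreach), response = 1 - prod_k (1 - p_k'), then
## mixed over the stratum weights.
oracle_expected_adherence <- function(config, p_outreach) {
  mod <- function(b, f) {
    o <- b / (1 - b) * f
    o / (1 + o)
  }
  cells <- expand.grid(named = c(TRUE, FALSE), out = c(TRUE, FALSE))
  w <- ifelse(cells$named, config$p_named, 1 - config$p_named) *
    ifelse(cells$out, p_outreach, 1 - p_outreach)
  q <- vapply(seq_len(nrow(cells)), function(i) {
    f <- config$personalization_effect^cells$named[i] *
      config$outreach_effect^cells$out[i]
    1 - prod(1 - mod(config$response_prob, f))
  }, numeric(1))
  sum(w * q)
}

## Small deterministic cohort builder for hand-constructed records.
make_record <- function(patient_id = "X1", index_date = "2018-06-04",
                        age = 30, gender = "female", ethnicity = "White",
                        diagnosis = "ARMS", patient_contact = TRUE,
                        clinician_contact = "valid", borough = "Croydon",
                        avail = c(0, 0, 0, 0), event_day = NA,
                        censor_day = 365) {
  data.frame(
    patient_id = patient_id, index_date = as.Date(index_date),
    age_at_index = age, gender = gender, ethnicity = ethnicity,
    index_diagnosis = diagnosis, patient_contact = patient_contact,
    clinician_contact = clinician_contact, borough = borough,
    avail_week_age = avail[1], avail_week_gender = avail[2],
    avail_week_ethnicity = avail[3], avail_week_diagnosis = avail[4],
    event_day = event_day, censor_day = censor_day,
    stringsAsFactors = FALSE
  )
}

table2_truth <- c(
  age = 0.010, male = 0.457, age_male = -0.009,
  Black = 0.995, Asian = 0.487, Mixed = 0.686, Other = 0.340,
  "Acute-transient-psychotic" = 1.169, "Substance-use" = -1.748,
  "Bipolar-mood" = 0.003, "Non-bipolar-mood" = -1.560, "Anxiety" = -2.006,
  "Personality" = -1.363, "Developmental" = -3.337,
  "Childhood-adolescence-onset" = -3.200,
  "Physiological-syndromes" = -2.310, "Mental-retardation" = -2.326
)
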