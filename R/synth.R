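## Category frequencies of the automatically screened population of the
## original deployment (counts over n = 3722). The substance-use count is
## 545 (14.6%); no ARMS presentations occurred in that intake stream, so the
## default ARMS share is 0 (configs that need identifiable diagnosis
## contrasts for model fitting should give ARMS a positive share).
screened_gender_counts <- c(female = 2310, male = 1412)
screened_ethnicity_counts <- c(White = 2249, Black = 660, Asian = 249,
                               Mixed = 166, Other = 398)
screened_diagnosis_counts <- c(
  "ARMS" = 0,
  "Acute-transient-psychotic" = 46,
  "Substance-use" = 545,
  "Bipolar-mood" = 99,
  "Non-bipolar-mood" = 1076,
  "Anxiety" = 1198,
  "Personality" = 181,
  "Developmental" = 57,
  "Childhood-adolescence-onset" = 240,
  "Physiological-syndromes" = 237,
  "Mental-retardation" = 43
)

#' Configuration of the synthetic EHR cohort generator
#'
#' Defines the statistical structure of a simulated intake stream:
#' demographic and diagnostic category frequencies (defaults: the
#' automatically screened population of the original deployment),
#' a truncated-normal age distribution, an entry-date window, a
#' predictor-missingness schedule (a fraction of patients incomplete at
#' entry, completed by a memoryless weekly process), Cox-model-driven
#' time-to-psychosis outcomes, administrative censoring with a small
#' per-day attrition hazard, and clinician-behaviour parameters.
#'
#' The outcome baseline hazard is calibrated (analytically, at config build
#' time) so that the expected six-month psychosis proportion of the
#' generated population matches `target_six_month` (default 38/3640, the
#' deployment's screened-population proportion); pass `baseline` to
#' override.
#'
#' @param n_patients number of patients in the intake stream.
#' @param gender_freq,ethnicity_freq,diagnosis_freq named non-negative
#'   weights per category (normalised internally). `diagnosis_freq` may
#'   include the screened-out classes `Organic` and `Psychotic` for
#'   eligibility testing.
#' @param age_mean,age_sd,age_min truncated-normal age distribution (years).
#' @param entry_start,entry_end entry-date window (defaults: the deployment
#'   window).
#' @param missing_frac fraction of patients with at least one predictor
#'   missing at entry (default 0.35). Only ethnicity and diagnosis can be
#'   late; age and gender are assumed present at entry.
#' @param weekly_completion_prob weekly probability that a missing predictor
#'   appears (memoryless).
#' @param true_betas [risk_coefficients()] used as generating truth.
#' @param baseline optional [baseline_survival()]; default calibrated to
#'   `target_six_month`.
#' @param target_six_month expected six-month event proportion used for
#'   baseline calibration.
#' @param followup_max_days administrative censoring (days from index).
#' @param attrition_rate per-day hazard of loss to follow-up; the default
#'   solves `1 - exp(-183 * h)` = the deployment's six-month
#'   loss-to-follow-up fraction (82/3722).
#' @param p_patient_contact probability that patient contact details exist.
#' @param p_contact_absent,p_contact_incorrect clinician-contact state
#'   probabilities (remainder: valid).
#' @param borough_freq named weights over the four catchment boroughs.
#' @param behaviour a [workflow_config()] with clinician response
#'   behaviour.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 3722,
                          gender_freq = screened_gender_counts,
                          ethnicity_freq = screened_ethnicity_counts,
                          diagnosis_freq = screened_diagnosis_counts,
                          age_mean = 37.5, age_sd = 18.4, age_min = 14,
                          entry_start = "2018-05-14",
                          entry_end = "2019-04-29",
                          missing_frac = 0.35,
                          weekly_completion_prob = 0.25,
                          true_betas = risk_coefficients(),
                          baseline = NULL,
                          target_six_month = 38 / 3640,
                          followup_max_days = 365,
                          attrition_rate = -log(1 - 82 / 3722) / 183,
                          p_patient_contact = 1,
                          p_contact_absent = 2 / 117,
                          p_contact_incorrect = 0.05,
                          borough_freq = c(Lambeth = 0.25, Croydon = 0.25,
                                           Lewisham = 0.25, Southwark = 0.25),
                          behaviour = workflow_config()) {
  norm_freq <- function(f, levels, field) {
    check_level(names(f), levels, field)
    stopifnot(all(f >= 0), sum(f) > 0)
    out <- setNames(rep(0, length(levels)), levels)
    out[names(f)] <- f / sum(f)
    out
  }
  stopifnot(n_patients >= 1, missing_frac >= 0, missing_frac <= 1,
            weekly_completion_prob > 0, weekly_completion_prob <= 1,
            age_sd > 0, followup_max_days > 0, attrition_rate >= 0,
            inherits(true_betas, "risk_coefficients"),
            inherits(behaviour, "workflow_config"))
  cfg <- structure(list(
    n_patients = n_patients,
    gender_freq = norm_freq(gender_freq, genders, "gender frequency"),
    ethnicity_freq = norm_freq(ethnicity_freq, ethnicities,
                               "ethnicity frequency"),
    diagnosis_freq = norm_freq(diagnosis_freq,
                               c(diagnoses, ineligible_diagnoses),
                               "diagnosis frequency"),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    entry_start = as.Date(entry_start), entry_end = as.Date(entry_end),
    missing_frac = missing_frac,
    weekly_completion_prob = weekly_completion_prob,
    true_betas = true_betas,
    target_six_month = target_six_month,
    followup_max_days = followup_max_days,
    attrition_rate = attrition_rate,
    p_patient_contact = p_patient_contact,
    p_contact_absent = p_contact_absent,
    p_contact_incorrect = p_contact_incorrect,
    borough_freq = norm_freq(borough_freq, boroughs, "borough frequency"),
    behaviour = behaviour
  ), class = "cohort_config")
  cfg$baseline <- if (is.null(baseline)) {
    calibrate_cohort_baseline(cfg)
  } else {
    stopifnot(inherits(baseline, "baseline_survival"))
    baseline
  }
  cfg
}

#' Expected event proportion of a cohort configuration
#'
#' Closed-form expectation of `1 - exp(-rate * t * exp(lp))` over the
#' configured covariate distribution (categorical cells exactly; age by
#' quadrature over the truncated normal).
#'
#' @param rate exponential baseline hazard per day.
#' @param config a [cohort_config()] (baseline not required).
#' @param t_days horizon in days.
#' @return Expected event probability by `t_days`.
#' @keywords internal
expected_event_proportion <- function(rate, config, t_days = 183) {
  ## age quadrature nodes on the truncated normal
  p_lo <- pnorm(config$age_min, config$age_mean, config$age_sd)
  qs <- p_lo + (1 - p_lo) * (seq_len(200) - 0.5) / 200
  ages <- qnorm(qs, config$age_mean, config$age_sd)

  dx_f <- config$diagnosis_freq[diagnoses]         # screened-out classes
  dx_f <- dx_f / sum(dx_f)                         # never reach scoring
  cells <- expand.grid(gender = genders, ethnicity = ethnicities,
                       diagnosis = diagnoses, stringsAsFactors = FALSE)
  w <- config$gender_freq[cells$gender] *
    config$ethnicity_freq[cells$ethnicity] * dx_f[cells$diagnosis]
  keep <- w > 0
  cells <- cells[keep, ]
  w <- w[keep]
  total <- 0
  for (i in seq_len(nrow(cells))) {
    lp <- linear_predictor(ages, cells$gender[i], cells$ethnicity[i],
                           cells$diagnosis[i], config$true_betas)
    total <- total + w[[i]] * mean(1 - exp(-rate * t_days * exp(lp)))
  }
  unname(total)
}

#' Calibrate the generator's baseline hazard
#'
#' Solves for the exponential baseline hazard under which the configured
#' covariate mix has expected six-month event proportion
#' `config$target_six_month`.
#'
#' @param config a [cohort_config()] (the `baseline` element is ignored).
#' @return A [baseline_survival()] of exponential form.
#' @export
calibrate_cohort_baseline <- function(config) {
  f <- function(r) {
    expected_event_proportion(r, config, 183) - config$target_six_month
  }
  rate <- uniroot(f, c(1e-9, 0.05), tol = 1e-12)$root
  baseline_survival("exponential", rate = rate)
}

#' Generate a synthetic EHR intake cohort
#'
#' Samples demographics independently per factor from the configured
#' frequencies, ages from the truncated normal, entry dates uniformly over
#' the window, contact availability, and predictor-missingness schedules
#' (a `missing_frac` share of patients has ethnicity and/or diagnosis
#' arriving late, with geometric weekly completion). Outcome columns are
#' filled by [sample_event_times()]. Deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param outcomes also draw event/censoring times (default `TRUE`).
#' @return A cohort data frame in the dialect of [read_cohort()].
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            outcomes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0L) stop("cohort must have at least one patient", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  set.seed(seeds[1])

  sample_cat <- function(freq) {
    names(freq)[sample.int(length(freq), n, replace = TRUE, prob = freq)]
  }
  p_lo <- pnorm(config$age_min, config$age_mean, config$age_sd)
  ages <- qnorm(p_lo + (1 - p_lo) * runif(n), config$age_mean, config$age_sd)

  days <- as.numeric(config$entry_end - config$entry_start)
  index_date <- config$entry_start + floor(runif(n) * (days + 1))

  contact_draw <- runif(n)
  clinician_contact <- ifelse(
    contact_draw < config$p_contact_absent, "absent",
    ifelse(contact_draw < config$p_contact_absent + config$p_contact_incorrect,
           "incorrect", "valid")
  )

  ## missingness schedule: ethnicity and/or diagnosis can be late
  incomplete <- runif(n) < config$missing_frac
  which_late <- sample(c("ethnicity", "diagnosis", "both"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2))
  delay <- function(active) {
    d <- rep(0, n)
    d[active] <- rgeom(sum(active), config$weekly_completion_prob) + 1L
    d
  }
  eth_late <- incomplete & which_late %in% c("ethnicity", "both")
  dx_late <- incomplete & which_late %in% c("diagnosis", "both")

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    index_date = index_date,
    age_at_index = ages,
    gender = sample_cat(config$gender_freq),
    ethnicity = sample_cat(config$ethnicity_freq),
    index_diagnosis = sample_cat(config$diagnosis_freq),
    patient_contact = runif(n) < config$p_patient_contact,
    clinician_contact = clinician_contact,
    borough = sample_cat(config$borough_freq),
    avail_week_age = 0,
    avail_week_gender = 0,
    avail_week_ethnicity = delay(eth_late),
    avail_week_diagnosis = delay(dx_late),
    event_day = NA_real_,
    censor_day = NA_real_,
    stringsAsFactors = FALSE
  )
  if (outcomes) {
    model <- risk_model(config$true_betas, config$baseline)
    cohort <- sample_event_times(cohort, model, config, seed = seeds[2])
  }
  cohort
}

#' Draw time-to-psychosis outcomes for a cohort
#'
#' Event times follow the Cox model by inverse-transform sampling from
#' `S(t|x) = S0(t)^exp(lp)`; with an exponential baseline,
#' `T = -log(U) / (rate * exp(lp))`. Censoring is the earlier of the
#' administrative follow-up end and an exponential attrition draw. Exactly
#' one of event/censoring terminates each patient's follow-up; times are
#' rounded up to whole days (day-granular records produce the event-time
#' ties the Efron correction is for). Outcomes are drawn from the true
#' covariates regardless of when they become visible to screening.
#'
#' @param cohort cohort data frame.
#' @param model a [risk_model()] with the generating truth.
#' @param config a [cohort_config()] (censoring parameters).
#' @param seed integer seed.
#' @return The cohort with `event_day`/`censor_day` filled.
#' @export
sample_event_times <- function(cohort, model, config, seed = 1L) {
  stopifnot(is.data.frame(cohort), inherits(model, "risk_model"),
            inherits(config, "cohort_config"))
  n <- nrow(cohort)
  set.seed(as.integer(seed))
  scoreable <- cohort$index_diagnosis %in% diagnoses
  lp <- rep(NA_real_, n)
  lp[scoreable] <- linear_predictor(
    cohort$age_at_index[scoreable], cohort$gender[scoreable],
    cohort$ethnicity[scoreable], cohort$index_diagnosis[scoreable],
    model$coeffs
  )
  u <- runif(n)
  t_event <- rep(Inf, n)
  if (model$baseline$form == "exponential") {
    rate <- model$baseline$rate
    if (rate > 0) {
      t_event[scoreable] <- -log(u[scoreable]) /
        (rate * exp(lp[scoreable]))
    }
  } else {
    st <- model$baseline$steps
    for (i in which(scoreable)) {
      s_i <- st$survival^exp(lp[i])
      hit <- which(s_i <= u[i])
      t_event[i] <- if (length(hit)) st$time[hit[1L]] else Inf
    }
  }
  attrition <- if (config$attrition_rate > 0) {
    rexp(n, config$attrition_rate)
  } else {
    rep(Inf, n)
  }
  censor <- pmin(config$followup_max_days, ceiling(attrition))
  event_day <- pmax(1, ceiling(t_event))
  is_event <- event_day <= censor
  cohort$event_day <- ifelse(is_event, event_day, NA_real_)
  cohort$censor_day <- ifelse(is_event, event_day, censor)
  cohort
}

#' Observed follow-up time and event flag of a cohort
#'
#' @param cohort cohort data frame with outcomes.
#' @return A data frame `time`, `event` (0/1).
#' @export
observed_followup <- function(cohort) {
  data.frame(
    time = ifelse(is.na(cohort$event_day), cohort$censor_day,
                  cohort$event_day),
    event = as.numeric(!is.na(cohort$event_day))
  )
}
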