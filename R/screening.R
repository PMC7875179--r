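#' Study configuration for the weekly screening loop
#'
#' @param start_date,end_date study window (coerced with [as.Date()]);
#'   the defaults are the deployment window of the original feasibility
#'   study (2018-05-14 to 2019-04-29).
#' @param threshold detection threshold on predicted risk at the horizon;
#'   the deployment used >= 5% at two years (an operational, not clinical,
#'   cut-off). Comparison is inclusive.
#' @param horizon_days risk horizon in days (default 730).
#' @param min_age minimum eligible age in years; the study recruited
#'   patients aged 14 or above, so eligibility is `age >= 14`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(start_date = "2018-05-14",
                         end_date = "2019-04-29",
                         threshold = 0.05,
                         horizon_days = 730,
                         min_age = 14) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(start_date < end_date, threshold > 0, threshold < 1,
            horizon_days > 0, min_age >= 0)
  structure(list(start_date = start_date, end_date = end_date,
                 threshold = threshold, horizon_days = horizon_days,
                 min_age = min_age),
            class = "study_config")
}

#' Eligibility for automatic screening
#'
#' A patient is eligible when (i) aged at least `min_age` at index, (ii) the
#' index diagnosis is a non-organic, non-psychotic cluster (any of the
#' calculator's 11 clusters, ARMS included), (iii) patient contact details
#' exist, and (iv) the index date falls within the study window.
#' Ineligibility is a value, not an error: the return names the first failed
#' rule.
#'
#' @param cohort cohort data frame (see [read_cohort()] for the column
#'   contract); one row per patient.
#' @param config a [study_config()].
#' @return Character vector, one per row: `"eligible"` or one of
#'   `"age"`, `"diagnosis"`, `"contact"`, `"window"`.
#' @export
check_eligibility <- function(cohort, config = study_config()) {
  stopifnot(is.data.frame(cohort), inherits(config, "study_config"))
  check_level(cohort$index_diagnosis, c(diagnoses, ineligible_diagnoses),
              "index_diagnosis")
  idx <- as.Date(cohort$index_date)
  reason <- rep("eligible", nrow(cohort))
  in_window <- idx >= config$start_date & idx <= config$end_date
  reason[!in_window] <- "window"
  reason[!cohort$patient_contact] <- "contact"
  reason[cohort$index_diagnosis %in% ineligible_diagnoses] <- "diagnosis"
  reason[cohort$age_at_index < config$min_age] <- "age"
  reason
}

#' Screen one patient at a given week offset
#'
#' Computes the weekly screening status of a single eligible patient at
#' `week_index` weeks after their entry week. If any predictor only becomes
#' available after `week_index` the status is `AWAITING_PREDICTORS`;
#' otherwise the two-year risk is computed once from the covariates at index
#' date and the patient is `SCREENED`, with `detected = (risk >= threshold)`
#' (inclusive).
#'
#' @param record one-row cohort data frame.
#' @param week_index non-negative week offset since the patient entered.
#' @param model a [risk_model()].
#' @param config a [study_config()].
#' @return A one-row data frame: `patient_id`, `week`, `status`, `risk`
#'   (NA unless screened), `detected`.
#' @export
screen_patient <- function(record, week_index, model, config = study_config()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L, week_index >= 0,
            inherits(model, "risk_model"), inherits(config, "study_config"))
  avail <- c(record$avail_week_age, record$avail_week_gender,
             record$avail_week_ethnicity, record$avail_week_diagnosis)
  avail[is.na(avail)] <- Inf
  if (any(avail > week_index)) {
    return(data.frame(patient_id = record$patient_id, week = week_index,
                      status = "AWAITING_PREDICTORS", risk = NA_real_,
                      detected = FALSE))
  }
  risk <- predict_risk(model, record$age_at_index, record$gender,
                       record$ethnicity, record$index_diagnosis,
                       horizon_days = config$horizon_days)
  data.frame(patient_id = record$patient_id, week = week_index,
             status = "SCREENED", risk = risk,
             detected = risk >= config$threshold)
}

#' Run the weekly automatic screening loop
#'
#' Iterates the study window in 7-day weeks from the start date. Each
#' eligible patient enters at the week containing their index date and is
#' re-checked every week until all predictors are available; risk is
#' computed once, at the first complete week, and detection raised when the
#' risk reaches the threshold. Patients whose predictors never complete
#' within the window end the study as `AWAITING_PREDICTORS`. The log carries
#' one terminal entry per patient and is fully reproducible from the inputs
#' (no cross-patient state).
#'
#' @param cohort cohort data frame.
#' @param model a [risk_model()].
#' @param config a [study_config()].
#' @return A list: `log` (data frame `patient_id, week, status, risk,
#'   detected`, `status` one of `INELIGIBLE(<reason>)`,
#'   `AWAITING_PREDICTORS`, `SCREENED`) and `detections` (the detected rows
#'   of the log, `week` being the week of first successful screening).
#' @export
run_weekly_screening <- function(cohort, model, config = study_config()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            inherits(model, "risk_model"))
  reasons <- check_eligibility(cohort, config)
  idx <- as.Date(cohort$index_date)
  entry_week <- pmax(0, as.integer(floor(
    as.numeric(idx - config$start_date) / 7
  )))
  last_week <- as.integer(floor(
    as.numeric(config$end_date - config$start_date) / 7
  ))

  avail <- cbind(cohort$avail_week_age, cohort$avail_week_gender,
                 cohort$avail_week_ethnicity, cohort$avail_week_diagnosis)
  avail[is.na(avail)] <- Inf
  complete_offset <- apply(avail, 1L, max)      # weeks after entry
  screen_week <- entry_week + complete_offset   # study week of screening

  eligible <- reasons == "eligible"
  screened <- eligible & screen_week <= last_week

  status <- ifelse(eligible,
                   ifelse(screened, "SCREENED", "AWAITING_PREDICTORS"),
                   paste0("INELIGIBLE(", reasons, ")"))
  week <- ifelse(screened, screen_week, ifelse(eligible, last_week, entry_week))

  risk <- rep(NA_real_, nrow(cohort))
  if (any(screened)) {
    risk[screened] <- predict_risk(
      model, cohort$age_at_index[screened], cohort$gender[screened],
      cohort$ethnicity[screened], cohort$index_diagnosis[screened],
      horizon_days = config$horizon_days
    )
  }
  detected <- !is.na(risk) & risk >= config$threshold

  log <- data.frame(patient_id = cohort$patient_id, week = as.integer(week),
                    status = status, risk = risk, detected = detected,
                    stringsAsFactors = FALSE)
  list(log = log, detections = log[log$detected, , drop = FALSE])
}

#' Retrospective diagnostic-lag filter
#'
#' The retrospective variant of the calculator excluded patients who
#' converted to psychosis within a lag window (three months) of their index
#' diagnosis, to mitigate ICD-10 diagnostic instability; the deployed
#' refined model drops this lag. The filter removes only observed early
#' converters — patients censored early without an event are retained.
#'
#' @param cohort cohort data frame with outcome columns populated.
#' @param lag_days non-negative lag in days (default 90).
#' @return The cohort subset with early converters removed.
#' @export
apply_diagnostic_lag_filter <- function(cohort, lag_days = 90) {
  stopifnot(is.data.frame(cohort))
  if (length(lag_days) != 1L || is.na(lag_days) || lag_days < 0) {
    stop("lag_days must be a single non-negative number", call. = FALSE)
  }
  drop <- !is.na(cohort$event_day) & cohort$event_day < lag_days
  cohort[!drop, , drop = FALSE]
}

## ---- cohort CSV dialect ----------------------------------------------------

cohort_columns <- c(
  "patient_id", "index_date", "age_at_index", "gender", "ethnicity",
  "index_diagnosis", "patient_contact", "clinician_contact", "borough",
  "avail_week_age", "avail_week_gender", "avail_week_ethnicity",
  "avail_week_diagnosis", "event_day", "censor_day"
)

#' Read and write the cohort CSV dialect
#'
#' One row per patient; ISO-8601 dates; empty cells mean missing (for
#' `avail_week_*`: the predictor never appears). `patient_contact` is
#' `true`/`false`; `event_day` is empty when no psychosis transition was
#' observed.
#'
#' @param path file path.
#' @return `read_cohort()` returns the cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(patient_id = "character"))
  missing <- setdiff(cohort_columns, names(x))
  if (length(missing)) {
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$index_date <- as.Date(x$index_date)
  x$patient_contact <- as.logical(x$patient_contact)
  x[, cohort_columns]
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort[, cohort_columns]
  out$patient_contact <- tolower(as.character(out$patient_contact))
  for (col in grep("^avail_week_", names(out), value = TRUE)) {
    out[[col]][is.infinite(out[[col]])] <- NA
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the screening log CSV
#'
#' Columns `patient_id, week, status, risk, detected`.
#'
#' @param log screening log data frame from [run_weekly_screening()].
#' @param path file path.
#' @export
write_screening_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE, na = "")
  invisible(path)
}
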