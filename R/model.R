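#' Coefficients of the transdiagnostic psychosis risk calculator
#'
#' Constructs the coefficient set of the published transdiagnostic risk
#' calculator: a Cox proportional-hazards linear predictor over age (years,
#' linear, uncentred), gender, an age-by-gender interaction, ethnicity and
#' index diagnosis cluster. Defaults are the published multivariable betas
#' from the calculator's derivation cohort (secondary mental healthcare,
#' n = 34,209). Reference levels (female, White ethnicity, ARMS index
#' designation) carry coefficient exactly 0 and cannot be overridden.
#'
#' @param beta_age per-year log-hazard increment.
#' @param beta_male log-hazard for male vs female.
#' @param beta_age_male additional per-year log-hazard increment applied to
#'   males only (age-by-gender interaction).
#' @param beta_ethnicity named numeric vector of log-hazards for the
#'   non-reference ethnicity levels (`Black`, `Asian`, `Mixed`, `Other`).
#' @param beta_diagnosis named numeric vector of log-hazards for the
#'   non-reference index diagnosis clusters (all levels of
#'   [diagnoses] except `ARMS`).
#'
#' @return An object of class `risk_coefficients`: a list with elements
#'   `age`, `male`, `age_male`, `ethnicity` (length 5, White = 0) and
#'   `diagnosis` (length 11, ARMS = 0).
#' @export
#' @examples
#' cf <- risk_coefficients()
#' cf$diagnosis[["Anxiety"]]
risk_coefficients <- function(beta_age = 0.010,
                              beta_male = 0.457,
                              beta_age_male = -0.009,
                              beta_ethnicity = c(
                                Black = 0.995, Asian = 0.487,
                                Mixed = 0.686, Other = 0.340
                              ),
                              beta_diagnosis = c(
                                "Acute-transient-psychotic" = 1.169,
                                "Substance-use" = -1.748,
                                "Bipolar-mood" = 0.003,
                                "Non-bipolar-mood" = -1.560,
                                "Anxiety" = -2.006,
                                "Personality" = -1.363,
                                "Developmental" = -3.337,
                                "Childhood-adolescence-onset" = -3.200,
                                "Physiological-syndromes" = -2.310,
                                "Mental-retardation" = -2.326
                              )) {
  stopifnot(
    is.numeric(beta_age), length(beta_age) == 1L,
    is.numeric(beta_male), length(beta_male) == 1L,
    is.numeric(beta_age_male), length(beta_age_male) == 1L
  )
  need_eth <- setdiff(ethnicities, "White")
  if (!setequal(names(beta_ethnicity), need_eth)) {
    stop("beta_ethnicity must be named exactly: ",
         paste(need_eth, collapse = ", "), call. = FALSE)
  }
  need_dx <- setdiff(diagnoses, "ARMS")
  if (!setequal(names(beta_diagnosis), need_dx)) {
    stop("beta_diagnosis must be named exactly: ",
         paste(need_dx, collapse = ", "), call. = FALSE)
  }
  eth <- c(White = 0, beta_ethnicity[need_eth])
  dx <- c(ARMS = 0, beta_diagnosis[need_dx])
  structure(
    list(
      age = beta_age, male = beta_male, age_male = beta_age_male,
      ethnicity = eth[ethnicities], diagnosis = dx[diagnoses]
    ),
    class = "risk_coefficients"
  )
}

#' @export
print.risk_coefficients <- function(x, ...) {
  cat("Transdiagnostic risk calculator coefficients (log-hazard scale)\n")
  cat(sprintf("  age: %+.3f /year   male: %+.3f   age x male: %+.3f /year\n",
              x$age, x$male, x$age_male))
  cat("  ethnicity (ref White):\n")
  print(round(x$ethnicity, 3))
  cat("  index diagnosis (ref ARMS):\n")
  print(round(x$diagnosis, 3))
  invisible(x)
}

#' Baseline survivor function
#'
#' The published calculator's baseline survivor function S0(t) (survival of
#' the reference-covariate subject) was never released; absolute risks are
#' therefore configuration-dependent. Two forms are supported: an
#' `exponential` baseline S0(t) = exp(-rate * t) with a constant hazard per
#' day, and a `step` baseline given as ordered (time, survival) pairs, as
#' would be exported from a Kaplan-Meier or Breslow estimate.
#'
#' @param form `"exponential"` or `"step"`.
#' @param rate baseline hazard per day (exponential form); must be >= 0.
#' @param steps data frame with columns `time` (days, strictly increasing)
#'   and `survival` (non-increasing, in (0, 1]); step form only.
#'
#' @return An object of class `baseline_survival`.
#' @seealso [calibrate_exponential_baseline()] for the shipped default.
#' @export
baseline_survival <- function(form = c("exponential", "step"),
                              rate = NULL, steps = NULL) {
  form <- match.arg(form)
  if (form == "exponential") {
    stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
    out <- list(form = form, rate = rate)
  } else {
    stopifnot(is.data.frame(steps), all(c("time", "survival") %in% names(steps)))
    if (is.unsorted(steps$time, strictly = TRUE)) {
      stop("step baseline: times must be strictly increasing", call. = FALSE)
    }
    if (any(diff(steps$survival) > 0) || any(steps$survival > 1) ||
        any(steps$survival <= 0)) {
      stop("step baseline: survival must be non-increasing and in (0, 1]",
           call. = FALSE)
    }
    out <- list(form = form, steps = steps[, c("time", "survival")])
  }
  structure(out, class = "baseline_survival")
}

#' Evaluate the baseline survivor function
#'
#' @param baseline a [baseline_survival()] object.
#' @param t_days vector of times in days, >= 0.
#' @return S0(t) for each time. A step baseline refuses to extrapolate past
#'   its last step.
#' @export
baseline_surv_at <- function(baseline, t_days) {
  stopifnot(inherits(baseline, "baseline_survival"), all(t_days >= 0))
  if (baseline$form == "exponential") {
    return(exp(-baseline$rate * t_days))
  }
  st <- baseline$steps
  if (any(t_days > max(st$time))) {
    stop("horizon beyond last step of the baseline survivor function ",
         "(no extrapolation)", call. = FALSE)
  }
  idx <- findInterval(t_days, st$time)
  ifelse(idx == 0L, 1, st$survival[pmax(idx, 1L)])
}

#' Linear predictor of the risk calculator
#'
#' Computes the log-hazard linear predictor relative to the reference
#' subject (age 0, female, White, ARMS):
#' `beta_age * age + beta_male * [male] + beta_age_male * age * [male] +
#' beta_ethnicity[e] + beta_diagnosis[d]`.
#'
#' All arguments are vectorised and recycled to a common length. Unknown
#' category labels and negative ages are errors naming the offending field.
#'
#' @param age_years age at index date in years, >= 0.
#' @param gender `"male"` or `"female"`.
#' @param ethnicity one of [ethnicities].
#' @param diagnosis one of [diagnoses].
#' @param coeffs a [risk_coefficients()] object.
#' @return Numeric vector of linear predictors (log-hazard scale).
#' @export
#' @examples
#' linear_predictor(25, "male", "Black", "Acute-transient-psychotic",
#'                  risk_coefficients())  # 2.646
linear_predictor <- function(age_years, gender, ethnicity, diagnosis,
                             coeffs = risk_coefficients()) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop("age_years must be non-negative and non-missing", call. = FALSE)
  }
  check_level(gender, genders, "gender")
  check_level(ethnicity, ethnicities, "ethnicity")
  check_level(diagnosis, diagnoses, "diagnosis")
  male <- as.numeric(gender == "male")
  coeffs$age * age_years + coeffs$male * male +
    coeffs$age_male * age_years * male +
    unname(coeffs$ethnicity[ethnicity]) +
    unname(coeffs$diagnosis[diagnosis])
}

#' Absolute risk at a horizon
#'
#' Converts a linear predictor into an absolute event probability through the
#' standard Cox survivor transform: `risk = 1 - S0(horizon)^exp(lp)`.
#'
#' @param lp linear predictor(s) on the log-hazard scale.
#' @param baseline a [baseline_survival()] object.
#' @param horizon_days positive horizon in days (default 730, i.e. two
#'   years).
#' @return Risk(s) in \[0, 1\].
#' @export
risk_at_horizon <- function(lp, baseline, horizon_days = 730) {
  stopifnot(is.numeric(horizon_days), length(horizon_days) == 1L,
            horizon_days > 0)
  s0 <- baseline_surv_at(baseline, horizon_days)
  1 - s0^exp(lp)
}

#' Bundle coefficients, baseline and horizon into a risk model
#'
#' @param coeffs a [risk_coefficients()] object.
#' @param baseline a [baseline_survival()] object.
#' @param horizon_days default risk horizon in days.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(coeffs = risk_coefficients(),
                       baseline = calibrate_exponential_baseline(),
                       horizon_days = 730) {
  stopifnot(inherits(coeffs, "risk_coefficients"),
            inherits(baseline, "baseline_survival"),
            horizon_days > 0)
  structure(list(coeffs = coeffs, baseline = baseline,
                 horizon_days = horizon_days),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Risk model: horizon %d days, %s baseline", x$horizon_days,
              x$baseline$form))
  if (x$baseline$form == "exponential") {
    cat(sprintf(" (rate %.3e /day)", x$baseline$rate))
  }
  cat("\n")
  print(x$coeffs)
  invisible(x)
}

#' Predict absolute risk for patient covariates
#'
#' Convenience wrapper combining [linear_predictor()] and
#' [risk_at_horizon()].
#'
#' @inheritParams linear_predictor
#' @param model a [risk_model()] object.
#' @param horizon_days horizon override; defaults to the model's horizon.
#' @return Risk(s) in \[0, 1\].
#' @export
predict_risk <- function(model, age_years, gender, ethnicity, diagnosis,
                         horizon_days = model$horizon_days) {
  lp <- linear_predictor(age_years, gender, ethnicity, diagnosis,
                         model$coeffs)
  risk_at_horizon(lp, model$baseline, horizon_days)
}

#' Calibrate an exponential baseline to a reference-subject risk
#'
#' The shipped default baseline fixes the constant baseline hazard so that a
#' chosen anchor subject (default: 25-year-old female, White, ARMS) has a
#' chosen risk at a chosen horizon (default: 20% at two years). Because the
#' deployed calculator's baseline survivor function is not public, absolute
#' risks produced by this package are calibration-dependent and should be
#' read as such.
#'
#' @param target_risk anchor risk in (0, 1).
#' @param horizon_days anchor horizon in days.
#' @param age_years,gender,ethnicity,diagnosis anchor subject covariates.
#' @param coeffs a [risk_coefficients()] object.
#' @return A [baseline_survival()] of exponential form.
#' @export
calibrate_exponential_baseline <- function(target_risk = 0.20,
                                           horizon_days = 730,
                                           age_years = 25,
                                           gender = "female",
                                           ethnicity = "White",
                                           diagnosis = "ARMS",
                                           coeffs = risk_coefficients()) {
  stopifnot(target_risk > 0, target_risk < 1)
  lp <- linear_predictor(age_years, gender, ethnicity, diagnosis, coeffs)
  ## 1 - exp(-rate * h * e^lp) = target  =>  rate = -log(1-target)/(h e^lp)
  rate <- -log(1 - target_risk) / (horizon_days * exp(lp))
  baseline_survival("exponential", rate = rate)
}

## ---- model file IO ---------------------------------------------------------

coeffs_to_flat <- function(coeffs) {
  c(list(age = coeffs$age, male = coeffs$male, age_male = coeffs$age_male),
    as.list(coeffs$ethnicity), as.list(coeffs$diagnosis))
}

flat_to_coeffs <- function(betas) {
  betas <- unlist(betas)
  need <- c("age", "male", "age_male", ethnicities, diagnoses)
  missing <- setdiff(need, names(betas))
  if (length(missing)) {
    stop("model file is missing betas: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(betas), need)
  if (length(extra)) {
    stop("model file has unknown betas: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (betas[["White"]] != 0 || betas[["ARMS"]] != 0) {
    stop("reference levels White and ARMS must carry beta 0", call. = FALSE)
  }
  risk_coefficients(
    beta_age = betas[["age"]], beta_male = betas[["male"]],
    beta_age_male = betas[["age_male"]],
    beta_ethnicity = betas[setdiff(ethnicities, "White")],
    beta_diagnosis = betas[setdiff(diagnoses, "ARMS")]
  )
}

#' Read and write risk model JSON files
#'
#' The on-disk model format is JSON with keys `betas` (flat named map:
#' `age`, `male`, `age_male`, and the ethnicity / diagnosis labels,
#' reference levels present with value 0), `baseline`
#' (`{form, rate}` or `{form, steps}`), and `horizon_days`. The packaged
#' `extdata/table2_default.json` carries the published coefficient table
#' verbatim with the calibrated default baseline.
#'
#' @param path file path.
#' @return `read_risk_model()` returns a [risk_model()];
#'   `write_risk_model()` returns `path` invisibly.
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- flat_to_coeffs(x$betas)
  b <- x$baseline
  baseline <- if (identical(b$form, "exponential")) {
    baseline_survival("exponential", rate = b$rate)
  } else {
    baseline_survival("step", steps = as.data.frame(b$steps))
  }
  risk_model(coeffs, baseline, horizon_days = x$horizon_days)
}

#' @rdname read_risk_model
#' @param model a [risk_model()] object.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  b <- unclass(model$baseline)
  jsonlite::write_json(
    list(betas = coeffs_to_flat(model$coeffs), baseline = b,
         horizon_days = model$horizon_days),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' The packaged default risk model
#'
#' The published coefficient table with the default calibrated exponential
#' baseline and a two-year horizon, read from the packaged JSON file.
#'
#' @return A [risk_model()].
#' @export
default_risk_model <- function() {
  read_risk_model(system.file("extdata", "table2_default.json",
                              package = "psyriskscreen", mustWork = TRUE))
}
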