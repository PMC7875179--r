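#' Clinician adherence
#'
#' The deployment's primary feasibility outcome: the proportion of prompted
#' clinicians who responded to the calculator's alert. Cases without
#' clinician contact (never prompted) are excluded from the denominator.
#'
#' @param cases alert case data frame (completed).
#' @return Proportion in \[0, 1\].
#' @export
adherence_proportion <- function(cases) {
  stopifnot(is.data.frame(cases))
  prompted <- sum(cases$state != "NO_CONTACT")
  if (prompted == 0) {
    stop("adherence is undefined: no case was ever prompted", call. = FALSE)
  }
  sum(cases$state == "RESPONDED") / prompted
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric point probabilities no
#' larger than that of the observed table; the odds ratio estimate is the
#' conditional maximum likelihood estimate with a central 95% exact
#' conditional confidence interval (the convention under which published
#' 2x2 comparisons of response rates are reported). A degenerate outcome
#' margin (no responder or no non-responder at all) yields p = 1 with an
#' undefined odds ratio, flagged rather than silently returned.
#'
#' @param table 2x2 matrix of non-negative counts; rows = groups,
#'   columns = outcome yes/no.
#' @return A list of class `test_result`: `estimate` (odds ratio),
#'   `ci_low`, `ci_high`, `p_value`, `method`, and `flags`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(44, 31, 15, 25), 2, byrow = TRUE))  # OR 2.35
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  flags <- character()
  if (any(colSums(table) == 0)) {
    flags <- "degenerate outcome margin: odds ratio undefined"
    return(structure(list(statistic = NA_real_, estimate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = 1, df = NA_real_,
                          method = "Fisher exact", flags = flags),
                     class = "test_result"))
  }
  ft <- fisher.test(table, conf.level = 0.95)
  structure(list(statistic = NA_real_,
                 estimate = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 p_value = ft$p.value, df = NA_real_,
                 method = "Fisher exact (conditional MLE odds ratio)",
                 flags = flags),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat(sprintf("  statistic = %.4f", x$statistic))
  if (!is.na(x$df)) cat(sprintf("  (df = %.2f)", x$df))
  if (!is.na(x$statistic)) cat("\n")
  if (!is.na(x$estimate)) {
    cat(sprintf("  estimate = %.2f (95%% CI %.2f-%.2f)\n",
                x$estimate, x$ci_low, x$ci_high))
  }
  cat(sprintf("  p = %.4g\n", x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Kaplan-Meier curve with Greenwood confidence intervals
#'
#' Product-limit estimate over the observed event times, with the classical
#' Greenwood variance and a plain (linear-scale) 95% confidence interval
#' `S +/- 1.96 SE`, clipped to \[0, 1\] (a log-log interval is available as
#' an option). At tied times, events precede censorings. Where the estimate
#' has dropped to zero the Greenwood variance is reported as zero and the
#' interval collapses.
#'
#' @param times positive observed times (days).
#' @param event_flags 0/1 event indicators.
#' @param conf_type `"plain"` (default) or `"log-log"`.
#' @return An object of class `survival_curve`: data frame fields `times`
#'   (distinct event times), `n_at_risk`, `n_events`, `survival`,
#'   `greenwood_var`, `ci_low`, `ci_high`; plus `n` and `max_time`.
#' @export
km_curve <- function(times, event_flags, conf_type = c("plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  n <- length(times)
  stopifnot(n >= 1L, length(event_flags) == n, all(times > 0))
  event_flags <- as.numeric(event_flags)
  stopifnot(all(event_flags %in% c(0, 1)))

  sf <- survival::survfit(
    survival::Surv(times, event_flags) ~ 1,
    conf.type = if (conf_type == "plain") "plain" else "log-log"
  )
  keep <- sf$n.event > 0
  surv <- sf$surv[keep]
  se <- sf$std.err[keep] * surv          # survfit std.err is on log S
  gvar <- se^2
  lo <- sf$lower[keep]
  hi <- sf$upper[keep]
  ## S = 0: Greenwood sum blows up while S^2 -> 0; variance is taken as 0
  zero <- surv <= 0
  gvar[zero] <- 0
  lo[zero] <- 0
  hi[zero] <- 0
  structure(list(
    times = sf$time[keep],
    n_at_risk = sf$n.risk[keep],
    n_events = sf$n.event[keep],
    survival = surv,
    greenwood_var = gvar,
    ci_low = pmin(pmax(ifelse(is.na(lo), 0, lo), 0), 1),
    ci_high = pmin(pmax(ifelse(is.na(hi), 1, hi), 0), 1),
    n = n, max_time = max(times), conf_type = conf_type
  ), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve (n = %d, %d event times, %s CI)\n",
              x$n, length(x$times), x$conf_type))
  print(data.frame(time = x$times, n_risk = x$n_at_risk,
                   n_event = x$n_events, survival = round(x$survival, 4),
                   ci_low = round(x$ci_low, 4),
                   ci_high = round(x$ci_high, 4)))
  invisible(x)
}

#' Cumulative incidence at a time point
#'
#' `1 - S(t)` with the confidence interval mirrored from the survival
#' interval, plus the number still at risk at `t`. Requests beyond the last
#' observed time reuse the last estimate and are flagged as extrapolated.
#'
#' @param curve a [km_curve()] object.
#' @param t_days non-negative time in days.
#' @return A list: `incidence`, `ci_low`, `ci_high`, `n_at_risk`,
#'   `extrapolated`.
#' @export
cumulative_incidence_at <- function(curve, t_days) {
  stopifnot(inherits(curve, "survival_curve"), t_days >= 0)
  extrapolated <- t_days > curve$max_time
  if (extrapolated) {
    warning("time beyond last observed time; using last estimate",
            call. = FALSE)
  }
  i <- findInterval(t_days, curve$times)
  if (i == 0L) {
    return(list(incidence = 0, ci_low = 0, ci_high = 0,
                n_at_risk = curve$n, extrapolated = extrapolated))
  }
  at_risk <- if (i < length(curve$times)) {
    ## risk set just after t: subjects still under observation
    curve$n_at_risk[i + 1L]
  } else {
    curve$n_at_risk[i] - curve$n_events[i]
  }
  list(incidence = 1 - curve$survival[i],
       ci_low = 1 - curve$ci_high[i],
       ci_high = 1 - curve$ci_low[i],
       n_at_risk = at_risk,
       extrapolated = extrapolated)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) over the pooled event
#' times, with the p-value from the chi-square tail. Undefined (and
#' signalled) when neither group has any event.
#'
#' @param timesA,eventsA times and 0/1 event flags of group A.
#' @param timesB,eventsB times and 0/1 event flags of group B.
#' @return A `test_result` with `statistic` (chi-square), `df` = 1 and
#'   `p_value`.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) >= 1L, length(timesB) >= 1L,
            length(eventsA) == length(timesA),
            length(eventsB) == length(timesB))
  if (sum(eventsA) + sum(eventsB) == 0) {
    stop("log-rank test is undefined: no events in either group",
         call. = FALSE)
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  structure(list(statistic = stat, estimate = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1, method = "Log-rank test", flags = character()),
            class = "test_result")
}

#' Two-sample t-test from summary statistics
#'
#' Independent two-tailed t-test computed from group means, standard
#' deviations and sizes, as needed when only published summary statistics
#' are available. Welch's unpooled form with Welch-Satterthwaite degrees of
#' freedom is the default; a pooled-variance Student form is provided as an
#' option.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param pooled use the pooled-variance Student t instead of Welch.
#' @return A `test_result` with `statistic` (t), `df`, `estimate`
#'   (mean difference) with 95% CI, and two-sided `p_value`.
#' @export
#' @examples
#' t_from_summary(37.51, 18.44, 3722, 39.05, 18.27, 88)  # t = -0.78
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0",
                                 call. = FALSE)
  diff <- mean1 - mean2
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t-test (pooled variance)"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t-test"
  }
  t <- diff / se
  crit <- stats::qt(0.975, df)
  structure(list(statistic = t, estimate = diff,
                 ci_low = diff - crit * se, ci_high = diff + crit * se,
                 p_value = 2 * pt(-abs(t), df), df = df,
                 method = method, flags = character()),
            class = "test_result")
}
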