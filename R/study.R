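#' Read a study configuration YAML
#'
#' The file holds up to five blocks: `study:` (screening window, threshold,
#' horizon, minimum age), `model:` (path to a risk-model JSON; the packaged
#' default when omitted), `cohort:` (generator overrides, or `file:` with a
#' cohort CSV to use instead of generating), `workflow:` (alert-escalation
#' behaviour) and `seed:`. Unknown keys are errors.
#'
#' @param path YAML file path.
#' @return A list of class `study_setup`: `study` ([study_config()]),
#'   `model` (a [risk_model()] read from `model$file`, or `NULL`, in which
#'   case [run_study()] screens with the cohort's generating calculator so
#'   that detection and the simulated outcome process share one baseline),
#'   `cohort` ([cohort_config()]), `cohort_file` (path or `NULL`),
#'   `workflow` ([workflow_config()]), `seed`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("study", "model", "cohort", "workflow", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config blocks: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  build <- function(fn, args, drop = character()) {
    args <- args[setdiff(names(args), drop)]
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
    do.call(fn, args)
  }
  study <- build(study_config, raw$study %||% list())
  ## NULL model: run_study screens with the cohort's generating calculator,
  ## keeping detection consistent with the simulated outcome process
  model <- if (!is.null(raw$model$file)) read_risk_model(raw$model$file)
  workflow <- build(workflow_config, raw$workflow %||% list())
  cohort_args <- raw$cohort %||% list()
  cohort_file <- cohort_args$file
  cohort <- build(cohort_config, c(cohort_args,
                                   list(behaviour = workflow)),
                  drop = c("file", "behaviour"))
  structure(list(study = study, model = model, cohort = cohort,
                 cohort_file = cohort_file, workflow = workflow,
                 seed = raw$seed %||% 1L),
            class = "study_setup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## polynomial rolling hash of the serialized configuration, for the manifest
config_hash <- function(setup) {
  bytes <- as.integer(serialize(
    setup[c("study", "cohort", "workflow", "seed")], NULL
  ))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one full screening study
#'
#' Wires the pipeline end to end: cohort (generated, or loaded from a CSV
#' named in the configuration), weekly screening, alert workflow on the
#' detections, and the feasibility statistics. Fully deterministic given
#' the seed; any stage failure aborts with the stage named and removes
#' partial outputs.
#'
#' @param config a YAML path or a [read_study_config()] result.
#' @param seed optional integer master seed (overrides the config's).
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `screening_log.csv`, `case_log.csv`, `report.json` and
#'   `manifest.json`.
#' @return A list of class `study_report`; see [render_report()] for the
#'   plain-text view.
#' @export
run_study <- function(config, seed = NULL, out_dir = NULL) {
  setup <- if (inherits(config, "study_setup")) {
    config
  } else {
    read_study_config(config)
  }
  seed <- as.integer(seed %||% setup$seed)
  seeds <- derive_seeds(seed, 2L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        unlink(file.path(out_dir, c("cohort.csv", "screening_log.csv",
                                    "case_log.csv", "report.json",
                                    "manifest.json")))
      }
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(setup$cohort_file)) {
      read_cohort(setup$cohort_file)
    } else {
      generate_cohort(setup$cohort, seed = seeds[1])
    }
  })
  model <- setup$model %||%
    risk_model(setup$cohort$true_betas, setup$cohort$baseline,
               setup$study$horizon_days)
  screening <- stage("screening",
                     run_weekly_screening(cohort, model, setup$study))
  cases <- stage("alerts", {
    opened <- open_case(screening$detections, cohort)
    run_alert_workflow(opened, setup$workflow, seed = seeds[2])
  })
  report <- stage("report",
                  feasibility_report(cohort, screening$log, cases,
                                     setup$study))
  report$seed <- seed

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      write_screening_log(screening$log,
                          file.path(out_dir, "screening_log.csv"))
      write_case_log(cases, file.path(out_dir, "case_log.csv"))
      jsonlite::write_json(unclass(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      manifest <- list(
        schema_version = "1",
        config_hash = config_hash(setup),
        seed = seed,
        package_version = as.character(utils::packageVersion("psyriskscreen")),
        rows = list(cohort = nrow(cohort),
                    screening_log = nrow(screening$log),
                    cases = nrow(cases)),
        outputs = c("cohort.csv", "screening_log.csv", "case_log.csv",
                    "report.json")
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  report
}

## proportion followed to `t` and events by `t`, among given follow-up rows
six_month_block <- function(fu, t_days = 183) {
  followed <- (fu$event == 1 & fu$time <= t_days) | fu$time >= t_days
  events <- fu$event == 1 & fu$time <= t_days
  list(n = nrow(fu), followed = sum(followed), events = sum(events),
       proportion = if (sum(followed) > 0) sum(events) / sum(followed)
                    else NA_real_)
}

#' Assemble the feasibility statistics of a completed run
#'
#' Computes the report blocks from the stage outputs: the alert funnel,
#' clinician adherence, the per-channel response distribution, the
#' personalization and outreach odds-ratio analyses (Fisher exact), the
#' six-month cumulative incidence (Kaplan-Meier at 183 days, Greenwood CI,
#' at-risk count) in the screened and detected strata, a log-rank test of
#' detected vs screened-not-detected, and the Welch t comparison of age
#' between screened and detected.
#'
#' @param cohort cohort data frame with outcomes.
#' @param log screening log.
#' @param cases completed alert cases.
#' @param config a [study_config()].
#' @return A list of class `study_report`.
#' @export
feasibility_report <- function(cohort, log, cases, config = study_config()) {
  funnel <- funnel_summary(cases)
  channels <- funnel$channels
  channel_block <- list(
    counts = as.list(channels),
    percent = as.list(round(100 * channels / max(funnel$responded, 1), 1))
  )
  adherence <- if (funnel$prompted > 0) adherence_proportion(cases)
               else NA_real_

  or_block <- function(tab) {
    res <- fisher_exact_2x2(tab)
    list(table = unname(split(tab, row(tab))),
         or = round(res$estimate, 2),
         ci_low = res$ci_low, ci_high = res$ci_high, p = res$p_value)
  }
  ors <- list(
    personalization = if (funnel$prompted > 0) {
      or_block(personalization_table(cases))
    },
    outreach = if (funnel$prompted > 0) or_block(outreach_table(cases))
  )

  screened_ids <- log$patient_id[log$status == "SCREENED"]
  detected_ids <- log$patient_id[log$detected]
  stratum_rows <- function(ids) cohort[cohort$patient_id %in% ids, ]
  incidence_block <- function(ids) {
    rows <- stratum_rows(ids)
    if (nrow(rows) == 0L) return(NULL)
    fu <- observed_followup(rows)
    six <- six_month_block(fu)
    if (sum(fu$event) == 0) {
      return(c(six, list(incidence = 0, ci_low = 0, ci_high = 0,
                         n_at_risk = sum(fu$time >= 183))))
    }
    ci <- cumulative_incidence_at(km_curve(fu$time, fu$event), 183)
    c(six, ci[c("incidence", "ci_low", "ci_high", "n_at_risk")])
  }

  logrank <- NULL
  not_detected <- setdiff(screened_ids, detected_ids)
  if (length(detected_ids) && length(not_detected)) {
    fu_d <- observed_followup(stratum_rows(detected_ids))
    fu_s <- observed_followup(stratum_rows(not_detected))
    if (sum(fu_d$event) + sum(fu_s$event) > 0) {
      lr <- logrank_test(fu_d$time, fu_d$event, fu_s$time, fu_s$event)
      logrank <- list(statistic = lr$statistic, p = lr$p_value)
    }
  }

  ttest <- NULL
  if (length(detected_ids) >= 2 && length(screened_ids) >= 2) {
    a_s <- stratum_rows(screened_ids)$age_at_index
    a_d <- stratum_rows(detected_ids)$age_at_index
    tt <- t_from_summary(mean(a_s), stats::sd(a_s), length(a_s),
                         mean(a_d), stats::sd(a_d), length(a_d))
    ttest <- list(t = tt$statistic, df = tt$df, p = tt$p_value)
  }

  structure(list(
    funnel = unclass(funnel)[c("detected", "no_contact", "prompted",
                               "responded", "excluded", "decisions",
                               "referred")],
    adherence = adherence,
    channels = channel_block,
    odds_ratios = ors,
    incidence = list(screened = incidence_block(screened_ids),
                     detected = incidence_block(detected_ids)),
    logrank_detected_vs_rest = logrank,
    age_ttest_screened_vs_detected = ttest,
    counts = list(cohort = nrow(cohort), screened = length(screened_ids),
                  detected = length(detected_ids))
  ), class = "study_report")
}

#' Plain-text rendering of a study report
#'
#' @param report a `study_report`.
#' @return Character vector of lines, invisibly; printed to the console.
#' @export
render_report <- function(report) {
  f <- report$funnel
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
  lines <- c(
    sprintf("Cohort: %d patients, %d screened, %d detected",
            report$counts$cohort, report$counts$screened,
            report$counts$detected),
    sprintf("Funnel: detected %d | no contact %d | prompted %d | responded %d | excluded %d | decisions %d | referred %d",
            f$detected, f$no_contact, f$prompted, f$responded, f$excluded,
            f$decisions, f$referred),
    sprintf("Adherence: %s", pct(report$adherence)),
    sprintf("Channels: EMAIL1 %d (%s%%) EMAIL2 %d (%s%%) EMAIL3 %d (%s%%) PHONE %d (%s%%)",
            report$channels$counts$EMAIL1, report$channels$percent$EMAIL1,
            report$channels$counts$EMAIL2, report$channels$percent$EMAIL2,
            report$channels$counts$EMAIL3, report$channels$percent$EMAIL3,
            report$channels$counts$PHONE, report$channels$percent$PHONE)
  )
  for (nm in names(report$odds_ratios)) {
    o <- report$odds_ratios[[nm]]
    if (!is.null(o)) {
      lines <- c(lines, sprintf("%s OR: %.2f (95%% CI %.2f-%.2f, p = %.3f)",
                                nm, o$or, o$ci_low, o$ci_high, o$p))
    }
  }
  for (nm in names(report$incidence)) {
    b <- report$incidence[[nm]]
    if (!is.null(b)) {
      lines <- c(lines, sprintf(
        "%s: %d/%d followed to 6 months, %d events (%s); KM incidence %.3f (95%% CI %.3f-%.3f, %d at risk)",
        nm, b$followed, b$n, b$events, pct(b$proportion), b$incidence,
        b$ci_low, b$ci_high, b$n_at_risk
      ))
    }
  }
  if (!is.null(report$logrank_detected_vs_rest)) {
    lines <- c(lines, sprintf("Log-rank detected vs rest: chisq %.2f, p = %.2g",
                              report$logrank_detected_vs_rest$statistic,
                              report$logrank_detected_vs_rest$p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.study_report <- function(x, ...) {
  render_report(x)
  invisible(x)
}

#' Replicate a study and summarise the feasibility metrics
#'
#' Re-runs [run_study()] `n_replicates` times with per-replicate seeds
#' derived from the master seed, collecting adherence, the two simulated
#' odds ratios and the six-month incidences; returns the per-replicate
#' values with medians and central 95% intervals.
#'
#' @param config a YAML path or [read_study_config()] result.
#' @param n_replicates number of replicates, >= 1.
#' @param seed master seed.
#' @return A list of class `replicate_summary`: `replicates` (data frame)
#'   and `summary` (data frame of median / lower / upper per metric).
#' @export
replicate_study <- function(config, n_replicates = 100, seed = 1L) {
  stopifnot(n_replicates >= 1)
  setup <- if (inherits(config, "study_setup")) {
    config
  } else {
    read_study_config(config)
  }
  seeds <- derive_seeds(seed, n_replicates)
  grab <- function(x, default = NA_real_) if (is.null(x)) default else x
  rows <- lapply(seq_len(n_replicates), function(i) {
    r <- run_study(setup, seed = seeds[i])
    data.frame(
      replicate = i,
      adherence = grab(r$adherence),
      or_personalization = grab(r$odds_ratios$personalization$or),
      or_outreach = grab(r$odds_ratios$outreach$or),
      incidence_screened = grab(r$incidence$screened$incidence),
      incidence_detected = grab(r$incidence$detected$incidence)
    )
  })
  reps <- do.call(rbind, rows)
  metrics <- setdiff(names(reps), "replicate")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- reps[[m]][is.finite(reps[[m]])]
    data.frame(metric = m, median = stats::median(v),
               lower = stats::quantile(v, 0.025, names = FALSE),
               upper = stats::quantile(v, 0.975, names = FALSE),
               n_finite = length(v))
  }))
  structure(list(replicates = reps, summary = summ),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicated study (%d replicates)\n", nrow(x$replicates)))
  print(transform(x$summary, median = round(median, 3),
                  lower = round(lower, 3), upper = round(upper, 3)))
  invisible(x)
}

#' Command-line entry point
#'
#' Backs the thin `inst/scripts/riskscreen.R` wrapper. Subcommands:
#' `run` (full pipeline; `--config`, `--seed`, `--out`), `replicate`
#' (`--replicates`), `simulate` (write a generated cohort CSV), and
#' `fixture-report` (funnel statistics of the packaged reference fixture).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: riskscreen <run|replicate|simulate|fixture-report>",
    "[--config PATH] [--seed INT] [--out DIR] [--replicates INT]"
  )
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out")
  cfg_path <- opt("--config")
  setup <- if (is.null(cfg_path)) {
    structure(list(study = study_config(), model = NULL,
                   cohort = cohort_config(), cohort_file = NULL,
                   workflow = workflow_config(), seed = seed),
              class = "study_setup")
  } else {
    read_study_config(cfg_path)
  }
  switch(
    cmd,
    run = {
      report <- run_study(setup, seed = seed, out_dir = out)
      render_report(report)
    },
    replicate = {
      n <- as.integer(opt("--replicates", "100"))
      print(replicate_study(setup, n_replicates = n, seed = seed))
    },
    simulate = {
      cohort <- generate_cohort(setup$cohort, seed = seed)
      path <- file.path(out %||% ".", "cohort.csv")
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, path)
      message("wrote ", path)
    },
    `fixture-report` = {
      fx <- make_reference_funnel_fixture()
      print(funnel_summary(fx$cases))
      cat(sprintf("adherence: %.1f%%\n",
                  100 * adherence_proportion(fx$cases)))
    },
    {
      message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(1L))
    }
  )
  invisible(0L)
}
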