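---
title: "Methods: screening simulation for a transdiagnostic psychosis risk calculator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening simulation for a transdiagnostic psychosis risk calculator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyriskscreen)
```

## The model

The calculator is a Cox proportional-hazards score over five routinely
recorded EHR predictors. For a patient with age $a$ (years, at index
date), gender $g$, ethnicity $e$ and index diagnosis cluster $d$,

$$\mathrm{lp} = \beta_a a + \beta_m [g{=}\mathrm{male}] +
\beta_{am}\, a\, [g{=}\mathrm{male}] + \beta_e + \beta_d, \qquad
\Pr(T \le t \mid x) = 1 - S_0(t)^{\exp(\mathrm{lp})}.$$

Reference levels (female, White, ARMS) carry coefficient exactly zero, so
the reference subject at age zero has $\mathrm{lp} = 0$. Age enters
linearly and uncentred — the published table gives a single per-year beta,
and non-linear age effects are explicitly future work. `risk_coefficients()`
ships the published betas; category labels are exact strings and unknown
labels are errors, never silently mapped.

**Baseline survivor function.** The deployed calculator's $S_0$ was never
published, so every absolute risk this package produces is
calibration-dependent. Two calibrations ship, each for a different
purpose, both exposed in configuration:

* the packaged model file (`default_risk_model()`) uses an exponential
  baseline fixed so that a 25-year-old female, White, ARMS subject has a
  two-year risk of 0.20 — a single, legible anchor for scoring patients in
  isolation;
* the cohort generator (`cohort_config()`) solves, at config-build time
  and in closed form (`calibrate_cohort_baseline()`), for the exponential
  rate under which its covariate mix has an expected six-month event
  proportion of 38/3640 ≈ 1.04%, the proportion observed in the deployment
  it emulates.

When `run_study()` is given no model file it screens with the cohort's own
generating calculator (same betas, same calibrated baseline), so that
detection and the simulated outcome process describe one coherent world;
mixing the 0.20-anchored scoring baseline with a 1%-anchored outcome
baseline would flag most of the cohort and emulate nothing.

## The screening loop

Eligibility requires age ≥ 14 at index (the deployment recruited patients
aged 14 or above, so the boundary is inclusive), a non-organic,
non-psychotic index cluster or an ARMS designation, existing patient
contact details and an index date inside the study window; ineligibility
is a value naming the first failed rule, not an error. Weeks are 7-day
blocks from the study start; a patient enters at the week containing their
index date and is re-checked weekly until all predictors are available.
Risk is computed once, at the first complete week, from covariates at the
index date — the deployment screened each individual once, and dynamic
re-scoring is future work. Detection is inclusive at the threshold
(risk ≥ 0.05 at 730 days).

The screening log records one terminal entry per patient
(`INELIGIBLE(reason)`, `AWAITING_PREDICTORS`, or `SCREENED` with risk and
detection flag). Weekly `AWAITING` rows would carry no information beyond
the completion week, which the log already implies, and would dominate the
file at realistic missingness; the loop's weekly semantics are tested
behaviourally instead.

The retrospective model variant excluded patients converting within 90
days of index; `apply_diagnostic_lag_filter()` reconstructs that rule and
removes only observed early converters — patients censored early without
an event are retained, since only converters are named by the rule.

## The alert-escalation machine

Each detection opens a case that escalates email1 → email2 →
email3/alternate contact → phone at one-week gaps, closing at the first
response or as `NO_RESPONSE` after the phone stage; cases without
clinician contact details never enter the machine. Four sequential stages
reconcile the deployment's described procedure (first email, third email
to an alternate contact, then phone) with its reported four response
channels.

Response behaviour is Bernoulli per stage. Personalization (patient name
vs Trust ID) and outreach (clinicians briefed in one borough) multiply
each channel's response odds. The defaults are a joint analytic solve of
six unknowns (four base probabilities, two modifiers) against six observed
quantities: the stage-wise conditional response rates 33/115, 20/82, 6/62,
30/56 and the aggregate odds ratios 2.35 (personalization, response by
email) and 2.02 (outreach, any response) under the deployed mix of 75/115
named alerts and 34/115 outreach cases. The solve lands at base
probabilities (0.174, 0.149, 0.056, 0.410) with modifiers 2.05 and 1.62.
Setting the per-channel modifiers to the aggregate odds ratios themselves
would overshoot: a multi-stage escalation amplifies a per-stage odds
effect, because the exposed group both responds more at each stage and is
depleted of non-responders sooner.

One subtlety of the published personalization comparison: its 2×2 counts
responders *by email* (44 + 15 = 59, the three email channels), not all 89
responders; `personalization_table()` reproduces exactly that contrast,
while `outreach_table()` counts response by any channel.

Exclusion is resolved before referral; excluded cases get no referral
decision. The packaged deterministic fixture
(`make_reference_funnel_fixture()`) reproduces every published funnel
margin exactly; its split of the 18 exclusions across categories
(10/4/2/1/1) and its joint personalization-by-outreach layout are
synthetic, since only the margins were published.

## Statistical conventions

* **Fisher's exact test** (`fisher_exact_2x2`): two-sided p by summing
  hypergeometric point probabilities at or below the observed table's; the
  odds ratio is the conditional maximum-likelihood estimate with a central
  95% exact interval. This is the only convention that reproduces the
  published 2.35 and 2.02 from the published counts — the sample
  cross-product ratios are 2.37 and 2.03.
* **t-tests from summaries** (`t_from_summary`): Welch's unpooled form
  with Welch–Satterthwaite degrees of freedom (this reproduces the
  published t = −0.78 from group summaries); a pooled option exists but is
  not the default.
* **Kaplan–Meier** (`km_curve`): product-limit estimate with Greenwood
  variance and a plain linear-scale 95% interval $S \pm 1.96\,SE$ clipped
  to $[0,1]$ (log-log available as an option). At tied times events
  precede censorings. Where $S$ reaches zero the Greenwood sum diverges
  while $S^2 \to 0$; the variance is reported as 0 and the interval
  collapses.
* **Harrell's C** (`harrells_c`): pairs are comparable when the shorter
  observed time is an event, or at tied times when exactly one member is
  an event; score ties count 0.5; no comparable pairs is an explicit
  error, not 0.5.
* **Cox refitting** (`fit_cox_pl`): Efron tie handling by default (the
  generator's day-granular times are heavily tied; Efron is the less
  biased standard), Breslow retained for cross-checking. Separation
  symptoms are surfaced via a `flags` field rather than silently returned.
* Times are integer days throughout; six months is 183 days and two years
  730. Report percentages are rounded to one decimal (two where a
  denominator above ~3000 warrants it).

## The synthetic generator: what it emulates, and what it does not

`generate_cohort()` samples gender, ethnicity and diagnosis independently
per factor from the deployment's screened-population frequencies (a joint
table can be supplied), ages from a normal (mean 37.5, SD 18.4) truncated
at 14, and entry dates uniformly over the study window. A 35% share of
patients is incomplete at entry; only ethnicity and diagnosis can be late
(age and gender come with registration), completing by a memoryless weekly
Bernoulli process (default 0.25/week). Outcomes are inverse-transform
draws from the Cox model itself — for the exponential baseline
$T = -\log U / (\lambda_0 e^{\mathrm{lp}})$ — censored by the earlier of
administrative follow-up (365 days) and exponential attrition whose rate
solves the deployment's observed six-month loss to follow-up (82/3722).
All draws descend from one master seed through derived substreams, so
cohorts regenerate identically across runs.

What it deliberately does not emulate: correlated demographics (only
marginals were published), free-text records, within-borough clinician
networks, and — importantly — the composition of the detected stratum.
Under a single proportional-hazards world calibrated to the screened
population's 1% six-month incidence, detection at the 5%/two-year
threshold sweeps in moderate-risk patients and the simulated detected
stratum's six-month incidence comes out near 2–3%, well below the ~9–12%
seen in the deployment, where detections were concentrated in bipolar and
acute-psychotic clusters. A generator matching both anchors would need a
non-proportional or mixture outcome process; we keep the single-model
world and note that passing tests demonstrate internal consistency of the
pipeline, not calibration of absolute detected-stratum risk to real EHRs.
The replication-envelope tests reflect the same point: they check that
simulated adherence matches its closed-form expectation and that simulated
odds ratios stay in a sanity envelope around the published values, not
that every published number re-emerges from simulation.

## Problem sizes and numerical checks in the test suite

Brute-force oracle comparisons run at n ≤ 500 (Kaplan–Meier) and n ≤ 200
(concordance, explicit double loop); chance-level concordance is checked
at n = 2000. Parameter recovery fits the full 17-coefficient model on
30,000-patient cohorts — one fit for Wald-interval coverage (at most two
of 17 coefficients may miss), ten replicates for bias, with the bias
tolerance floored at the Monte Carlo precision each coefficient affords.
The recovery cohorts give ARMS a 2% share: the screened population
contains no ARMS presentations, and with an empty reference category the
diagnosis contrasts are unidentifiable. Log-rank type-I error uses 10,000
label permutations of a 200-subject null dataset against the 0.04–0.06
band. Replication envelopes use 200–1000 simulated alert workflows on a
~100-detection cohort. These sizes keep the default suite to a few
minutes on one CPU while leaving each check's Monte Carlo error well
inside its assertion band.

## Known limitations

Absolute risks are calibration-dependent (no published baseline); the
detected-stratum incidence is structurally lower than in the real
deployment (above); exclusion-category and non-referral-reason breakdowns
are synthetic beyond their published totals; the eligibility step takes
diagnosis clusters as given labels rather than mapping raw ICD-10 codes;
and whether the deployed system computed risk at two years from index or
from the (possibly later) screening date is unknown — this package uses
the index date, so a screening delay never changes a patient's risk.
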