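# Full study-replication configuration: a synthetic intake stream the size
# of the original deployment (3722 patients over the 2018-05-14..2019-04-29
# window), screened weekly at the >=5% two-year risk threshold, with the
# default clinician-behaviour model. All omitted keys take package defaults.
study:
  start_date: "2018-05-14"
  end_date: "2019-04-29"
  threshold: 0.05
  horizon_days: 730
  min_age: 14
cohort:
  n_patients: 3722
  missing_frac: 0.35
  weekly_completion_prob: 0.25
workflow:
  step_gap_weeks: 1
seed: 20180514
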