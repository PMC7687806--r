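# Demo pipeline configuration: a small simulated cohort run end to end.
seed: 42
episode_hours: 72
temp_threshold: 31
mortality_within_infection: true
ci_method: hanley
windows: {HR: 3, RR: 3, SBP: 3, TEMP: 17}
cohort:
  n_encounters: 150
  seed: 42
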