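# Example run configuration for read_run_config(). Unstated keys fall back
# to package defaults; all bundled parameter values are synthetic fixtures.
cohort_size: 20000
master_seed: 1
wtp: 20000
discount_rate: 0.035
screening:
  attendance: 0.80
  biopsy_compliance: 0.90
  biopsy_sensitivity: 0.90
survival:
  hr: 0.56
  as_switch_prob_7y: 0.30
  cure: {c_max: 0.8, beta: 0.2}
ppv:
  screen: 0.227
  clinical: 0.358
grid:
  start_range: [50, 55]
  stop_cap: 69
  intervals: [1, 2, 3, 4, 8]
  single_ages: [50, 69]
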