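# Buccal orodispersible formulation study: n = 17 poor sleepers,
# placebo / 20 ug / 40 ug crossover. PK targets and sleep condition effects
# are the cohort values this preset is calibrated to.
name: buccal
design:
  n_subjects: 17
  conditions: [placebo, dex20, dex40]
  time_in_bed_h: 8
  seed: 1
pk:
  targets:
    placebo: null
    dex20: {tmax_h: 1.29, thalf_h: 3.56, cmax_ng_ml: 0.11}
    dex40: {tmax_h: 1.73, thalf_h: 3.83, cmax_ng_ml: 0.24}
  bsv_cv: 0.25
  residual_cv: 0.05
  loq: 0.01
  lod: 0.005
sleep:
  effects:
    dex20: {sleep_latency: -9.5, rem_latency: 55.0, n2: 26.2, n3: 3.8}
    dex40: {sleep_latency: -11.5, rem_latency: 115.3, n2: 27.4, n3: 9.8, rem: -18.6}
eeg:
  enabled: false
  fs_raw: 128
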