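# Sublingual orodispersible formulation pilot: n = 8 good sleepers.
# Good sleepers fall asleep quickly under placebo, so latency effects are
# absent; the drug prolongs N2(+N3) and delays REM onset.
name: sublingual
design:
  n_subjects: 8
  conditions: [placebo, dex20, dex40]
  time_in_bed_h: 8
  seed: 1
pk:
  targets:
    placebo: null
    dex20: {tmax_h: 1.78, thalf_h: 3.64, cmax_ng_ml: 0.08}
    dex40: {tmax_h: 1.38, thalf_h: 5.92, cmax_ng_ml: 0.12}
  bsv_cv: 0.38
  residual_cv: 0.05
  loq: 0.01
  lod: 0.005
sleep:
  baseline: {sleep_latency: 12, rem_latency: 70, n1: 35, n2: 235, n3: 80, rem: 93, waso: 25}
  effects:
    dex20: {rem_latency: 80.1, n2: 17.8, n3: 6.6}
    dex40: {rem_latency: 97.8, n2: 18.0, n3: 11.0, rem: -14.7}
eeg:
  enabled: false
  fs_raw: 128
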