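# Default simulated experiment: no-odor control, a yeast-paste-like
# attractant, and a DEET-like repellent, n = 10 larvae per group,
# 5-min assays sampled at 1 Hz in a 10-cm arena.
arena:
  diameter_mm: 100
baseline:
  p_move: 0.6
  step_mean_mm: 2.0
  step_cv: 0.6
  p_big_turn: 0.15
  wobble_deg: 20
duration_s: 300
sample_interval_s: 1
seed: 20260922
groups:
  - label: control
    n_larvae: 10
    effect:
      mode: neutral
  - label: yeast
    n_larvae: 10
    effect:
      mode: attractant
      dose: 1.6        # mg/ml, as labeled
      dose_ref: 0.016
      strength: 0.5
  - label: DEET
    n_larvae: 10
    effect:
      mode: repellent
      dose: 1.0e-3     # v/v dilution, as labeled
      dose_ref: 1.0e-5
      strength: 0.5
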