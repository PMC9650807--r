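instruments:
  dash:
    scale_min: 0.0
    scale_max: 100.0
    direction: higher_is_worse
  constant:
    scale_min: 0.0
    scale_max: 100.0
    direction: higher_is_better
  pain_rest:
    scale_min: 0.0
    scale_max: 10.0
    direction: higher_is_worse
    resolution: 1.0
  pain_activities:
    scale_min: 0.0
    scale_max: 10.0
    direction: higher_is_worse
    resolution: 1.0
seed: 314.0
n_boot: 200.0
n_boot_auc: 200.0
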