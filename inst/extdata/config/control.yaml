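# Control condition: pattern 2 (V2-A2-S2) without the trauma input; the
# memory trace forms but fades over the cue-only trials.
seed: 1
protocol:
  name: control
  n_trials: 35
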