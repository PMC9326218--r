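# Resilient model: PFC firing threshold halved; fear extinguishes
# spontaneously under cue re-exposure while the memory is retained.
seed: 1
protocol:
  name: resilient
  n_trials: 35
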