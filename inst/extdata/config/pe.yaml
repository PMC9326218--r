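# Prolonged exposure: 10 establishment trials, then 20 sessions of engram
# recall + safety signal with a frozen-learning V1 test after each.
seed: 1
protocol:
  name: pe
  n_sessions: 20
  establishment_trials: 10
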