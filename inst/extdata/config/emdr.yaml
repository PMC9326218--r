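# EMDR: as PE, but with the fitted dorsolateral-PFC parameters
# (phi = 1.3, psi = 5) applied from therapy onset.
seed: 1
protocol:
  name: emdr
  n_sessions: 20
  establishment_trials: 10
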