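# Trauma establishment: 35 trials, single-cue baseline, pattern + trauma in
# trial 2, then repeated cue re-exposure (the PTSD-developing model).
seed: 1
protocol:
  name: trauma
  n_trials: 35
  trial_steps: 10000
  trauma_trial_steps: 30000
  interval_steps: 10000
  trauma_amplitude: 1
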