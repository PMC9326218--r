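# Grid-search fitting of a symptom curve over (phi, psi): phi 0.5-2.0 in
# steps of 0.05, psi 0.5-8.5 in steps of 0.5 (527 lattice points).
seed: 1
protocol:
  name: emdr
  n_sessions: 20
fitting:
  phi_range: [0.5, 2.0]
  phi_step: 0.05
  psi_range: [0.5, 8.5]
  psi_step: 0.5
  trials_per_session: 4
  method: mean
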