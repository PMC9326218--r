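# Mild emotional engagement: resilient PFC, weak trauma input during the
# pattern trial; the memory persists without a fear response.
seed: 1
protocol:
  name: mild
  trauma_amplitude: 0.1
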