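# Hardware-aware simulation demo. Noise magnitudes are placeholders, NOT
# calibrated to any chip.
hidden: 30
delay_kind: axonal
epochs: 150
noise:
  spike_jitter_sigma: 0.01
  fixed_pattern_sigma: 0.05
  weight_bits: 6
  delay_bits: 8
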