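# Example configuration for `ihmt sweep`: white-matter ihMT contrast over
# flip angle and band offset at fixed whole-sequence B1rms.
tissue: white_matter_1p5T
sequence:
  readout: bssfp
  TR_ms: 5
  tau_ms: 2
sweep:
  flips_deg: [10, 50, 2]     # from, to, by
  deltas_khz: [4, 12, 0.5]   # from, to, by
  b1rms_ut: 5
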