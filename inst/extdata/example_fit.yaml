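# Example configuration for `ihmt make-phantom` and `ihmt fit`.
# 1) ihmt make-phantom --config this.yaml --out pl161 --seed 1
# 2) point fit.data at the generated pl161_phantom.csv and run
#    ihmt fit --config this.yaml --out pl161 --seed 1
tissue: PL161
phantom:
  snr: 100
  scale: 100
acquisition:
  TR_ms: 5
  TE_ms: 2.5
  tau_ms: 2.2
  delta_khz: 8
  b1rms_ut: 4.2
fit:
  data: pl161_phantom.csv
  free: [R1f, R2f, M0s]
  n_starts: 4
  n_bootstrap: 0
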