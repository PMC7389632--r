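# Example run configuration. Every key is optional; absent keys take the
# packaged lisinopril defaults (logP -1.22, MW 405.48, pKa 2.5, solubility
# 97000 mg/L, no protein binding, renal elimination only, 30-min/80%
# first-order release). Kinetic parameters listed under `drug` are
# pre-calibration starting values; run the calibrate stage to replace them.
regimen:
  dose_mg: 20
  fed: false
dosefind:
  n: 100
  seed: 1
output:
  dir: pedpbpk_output
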