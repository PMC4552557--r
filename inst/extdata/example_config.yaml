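# Reference oscillatory configuration: gamma = 1e8 via k_minus_1 = 0.6/s.
# Parameter entries may be bare numbers or "value unit" strings; units,
# when present, must match the canonical um/s system exactly.
params:
  k_plus_1: 6 1/s
  k_minus_1: 0.6 1/s
  k_plus_2: 0.1 um/s
  k_minus_2: 0.01 1/s
  k_plus_2c: 0.01 um^3/s
  k_minus_2c: 0.001 um^2/s
  k_plus_3: 0.4 um^3/s
  k_minus_3: 0.04 1/s
  k_plus_4: 1 1/s
  k_minus_4: 1e-5 um^4/s
  D_D: 16 um^2/s
  D_E: 10 um^2/s
  N_D: 2000
  N_E: 700
  R: 0.5 um
  L: 4 um
geometry:
  dr: 0.1
  dz: 0.1
solver:
  t_end: 600
  sample_dt: 0.5
  rtol: 1.0e-6
  atol: 1.0e-9
analysis:
  threshold: 1.0e-3
  transient_frac: 0.5
  n_periods: 5
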