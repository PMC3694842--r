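# Reference configuration: calibrated parameter set for the reduced
# IkB--NF-kB delayed feedback models (concentrations nM, time min).
params:
  nf_tot: 250.0
  c0: 0.00185
  c1: 61.0
  deg_a: 0.07
  r_ikk: 0.14
  rho: 2.0
  kp: 600.0
  kc: 5.0e-7
  tau1: 45.0
  tau2: 45.0
  eps: 0.7
  c0_e: 2.0e-4
  deg_e: 0.25
signal:
  amplitude: 1.0
  t_on: 0.0
  duration: .inf
  baseline: 0.0
seed: 1
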