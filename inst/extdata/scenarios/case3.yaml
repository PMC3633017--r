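model: case3
label: case3
horizon_days: 600
params:
  a: 0.18
  aa: 1
  alpha: 0.001
  c: 0.035
  g1: 20000000
  g2: 100000
  g3: 20000000
  g4: 1000
  gamma: 10
  mu1: 0.03
  mu2: 10
  mu3: 10
  p1: 0.1245
  p2: 0.27
  p3: 5
  p4: 2.84
  q1: 10
  q2: 0.1121
  theta: 1000000
  K: 1.0e+10
initial_state:
  T: 1
  E: 1
  I: 10
  S: 0
provenance: published parameter table of the Arciero-type
  effector/tumour/IL-2/TGF-beta case study
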