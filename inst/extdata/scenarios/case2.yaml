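model: case2
label: case2
horizon_days: 600
params:
  a: 0.18
  b: 1.0e-09
  c: 0.05
  aa: 1
  g2: 100000
  s1: 0
  s2: 0
  mu2: 0.03
  p1: 0.1245
  g1: 20000000
  p2: 5
  g3: 1000
  mu3: 10
initial_state:
  T: 50
  E: 10
  I: 0
provenance: published parameter table of the Kirschner-Panetta-type
  effector/tumour/IL-2 case study (untreated, high antigenicity)
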