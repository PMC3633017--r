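model: case1
label: case1-s1
horizon_days: 100
params:
  a: 1.636
  b: 0.002
  n: 1
  p: 1.131
  g: 20.19
  m: 0.00311
  d: 0.1908
  s: 0.318
initial_state:
  T: 50
  E: 5
provenance: b, d, s, initial cell counts and 100-day horizon from the published scenario table; a, n, p, g, m are external defaults from the dimensionless Kuznetsov et al. (1994) effector-tumour model
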