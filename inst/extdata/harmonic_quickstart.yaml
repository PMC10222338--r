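name: harmonic_quickstart
seed: 42
system:
  kind: harmonic
  k_low: 1.0
  k_high: 4.0
  offset: 0.5
  kT: 0.6
equilibrate:
  n_equil_steps: 2000
  n_prod_steps: 8000
  save_every: 40
  n_replicates: 4
select:
  stride: 4
switch:
  schedule: L1
  n_steps: 500
  directions:
    - forward
    - backward
estimate:
  methods:
    - jar
    - cro
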