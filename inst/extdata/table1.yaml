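# Reference parameter preset for the Wilson-Cowan motion models.
task: simulate-point
preset: table1
params:
  w_ee: 12
  w_ei: 10
  w_ie: 10
  w_ii: 1
  b_e: 1.75
  b_i: 2.6
  tau_e: 5
  tau_i: 10
  sigma_e: 0.05
  sigma_i: 0.15
  delta: 0.02
  alpha: 1
  dx: 0.01
seed: 1
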