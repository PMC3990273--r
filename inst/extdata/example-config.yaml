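# Example configuration: the heterogeneous pair of the worked examples
# (sigma = 10 and 5 mV, shared sech kernel, common threshold).
model:
  sigma_v1: 10
  sigma_v2: 5
  psi: 9.64
  r: 0.7
  kernel:
    family: sech
    tau_s: 20
computation:
  tau_max: 100
  n_tau: 41
  n_max: 10
  Q: 10
simulation:
  dt: 0.4
  duration: 20000
  n_realizations: 200
  bin_T: 1000
seed: 42
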