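{
  "P": 1000,
  "T": 40000,
  "lam": 250,
  "nu": 0,
  "epsilon": 0.25,
  "sigma": 0.1,
  "n0": 0.5,
  "p_low0": 0.5,
  "seed": 1,
  "record_stride": 10,
  "tail_window": 100,
  "ah_window": 10000,
  "diagnostics": false,
  "beta1": 0.63,
  "beta2": 0.44,
  "beta3": -0.44,
  "rho": 0.9,
  "eta": 0.7,
  "phi": 100,
  "deltaH0": 0.3,
  "deltaL0": 0.05,
  "DeltaL1": 0.7,
  "DeltaH1": 0.45
}
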