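{
  "description": "Numerical constants of a distilled committor model for gas-hydrate nucleation exhibiting a temperature-dependent mechanism switch. The functional form is not reproduced here; the constants are recorded as reference metadata only and no evaluation is performed against them.",
  "constants": {
    "alpha": 0.0502,
    "beta": 3.17,
    "gamma_per_K": 0.109,
    "delta": 0.0149,
    "n_w0": 2,
    "T0_K": 270
  }
}
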