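{
  "_comment": "Default pipeline configuration. Provenance: tau, d and worked_examples are published example values; all other entries are repo defaults. Units: um, s, uM.",
  "tau": 0.04,
  "d": 2,
  "sigma_conc": 5,
  "ca_threshold": 0.6,
  "ca_basal": 0.1,
  "D_min": 5,
  "D_max": 130,
  "n_grid": 16,
  "gamma_min": 2,
  "gamma_max": 30,
  "spacing": "linear",
  "beta_lo": 0.5,
  "beta_hi": 1.0,
  "gamma_band": [0.1, 100],
  "worked_examples": {
    "D": [190, 15, 190, 15],
    "tau": [0.04, 0.04, 0.04, 0.04],
    "d": [2, 2, 0.02, 0.02]
  }
}
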