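{
  "b1": 0.25,
  "k1_max": 6,
  "K_M": 500,
  "k2_0": 0.392857142857143,
  "s2": 0.02,
  "b2": 0.5,
  "b3": 0.04,
  "f_tsl": 0.2,
  "p_fusion": 0.6,
  "n_sites": 24,
  "q": 32,
  "units": {
    "b1": "1/s",
    "k1_max": "1/s",
    "K_M": "nM",
    "k2_0": "1/s",
    "s2": "1/(s*nM)",
    "b2": "1/s",
    "b3": "s",
    "f_tsl": "fraction",
    "p_fusion": "probability",
    "n_sites": "count",
    "q": "pA"
  }
}
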