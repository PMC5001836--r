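{
  "seed": 11,
  "n_plates": 2,
  "n_planted_hits": 2,
  "n_decoys": 2,
  "noise_sd": 0.1,
  "positional_gradient": [0.02, 0.01],
  "primary_cutoff": -3.2,
  "secondary_min_hits": 2,
  "tertiary_max_ratio": 0.7
}
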