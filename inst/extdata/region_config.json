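{
  "B": { "phi": [-180, 0], "psi_hi": 50, "psi_lo": -120 },
  "A": { "phi": [-180, 0], "psi": [-120, 50] },
  "L": { "phi": [0, 180], "psi": [-50, 100] },
  "chi1_edges": [-120, 0, 120]
}
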