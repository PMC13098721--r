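{
  "model": "pendulum",
  "kappa2_mode": "dynamic",
  "rotation": { "D_rot_D": null, "D_rot_A": null,
                "paper_units_D": 15, "paper_units_A": 150 }
}
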