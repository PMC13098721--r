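{
  "model": "iso_spring",
  "kappa2_mode": "static",
  "spring": { "anisotropy_p": 1.0 }
}
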