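{
  "l_bond_nm": 0.154,
  "theta_bond_deg": 109.5,
  "k_bond_printed": 1e10,
  "k_bond_units_note": "Printed literature value for a single C-C bond spring constant, '1010 N/nm' as typeset; magnitude and units are ambiguous (likely a typesetting artifact of 10^10 with an unstated prefix). Carried verbatim as metadata; the simulation engine uses friction-scaled rate constants set in presets instead.",
  "kB_J_per_K": 1.380649e-23,
  "water_viscosity_mPas_25C": 0.89,
  "default_T_K": 298
}
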