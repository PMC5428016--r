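{
  "comment": "Literature uptake and transport parameters for the two nutrients that limit 3D tissue culture. Typical values are for EMT6/Ro, the best-characterized cell line for uptake and diffusion constants. Glucose diffusion constants are standard aqueous/tissue literature values (not cell-line specific) and are used for all presets.",
  "rho_cell_cells_per_uL": { "minimum": 2.1e5, "maximum": 4.0e5, "typical": 2.8e5 },
  "glucose": {
    "q_max_mol_per_cell_s": { "minimum": 2.7e-18, "maximum": 2.5e-16, "typical": 3.9e-17 },
    "k_M_mM": { "minimum": 4e-2, "maximum": 6e-2, "typical": 4e-2 },
    "D_M_cm2_s": { "minimum": 6.7e-6, "maximum": 6.7e-6, "typical": 6.7e-6 },
    "D_T_cm2_s": { "minimum": 1.1e-6, "maximum": 1.1e-6, "typical": 1.1e-6 },
    "c0_mM": 11,
    "c_sat_equals_c0": true
  },
  "oxygen": {
    "q_max_mol_per_cell_s": { "minimum": 1.7e-18, "maximum": 7.0e-16, "typical": 7.4e-17 },
    "k_M_mM": { "minimum": 4.6e-3, "maximum": 6.9e-3, "typical": 4.63e-3 },
    "D_M_cm2_s": { "minimum": 2e-5, "maximum": 3.35e-5, "typical": 2.44e-5 },
    "D_T_cm2_s": { "minimum": 9.5e-6, "maximum": 3.6e-5, "typical": 1.85e-5 },
    "c_sat_M_mM": 0.21,
    "c_sat_T_mM": 1.02
  }
}
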