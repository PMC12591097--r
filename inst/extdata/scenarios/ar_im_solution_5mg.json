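{
  "drug": {
    "name": "aripiprazole",
    "mw_g_mol": 448.38, "logp": 5.2, "pka": 7.6,
    "rbp": 0.61, "fup": 0.0317,
    "s_ref_mg_ml": 0.004, "ph_ref": 7, "solubility_factor": 660.92
  },
  "dose": {
    "ar_equivalent_dose_mg": 5, "route": "im_solution",
    "injection_volume_ml": 0.67
  },
  "depot": {
    "kp": 1.84, "fut": 0.0012, "perfusion_ml_min_100g": 9.6,
    "ecf_fraction": 0.118
  },
  "horizon_h": 168
}
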