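{
  "drug": {
    "name": "aripiprazole",
    "mw_g_mol": 448.38, "logp": 5.2, "pka": 7.6,
    "rbp": 0.61, "fup": 0.0317,
    "s_ref_mg_ml": 0.004, "ph_ref": 7, "solubility_factor": 660.92
  },
  "dose": {
    "ar_equivalent_dose_mg": 2, "route": "iv_infusion",
    "infusion_duration_h": 1
  },
  "horizon_h": 72
}
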