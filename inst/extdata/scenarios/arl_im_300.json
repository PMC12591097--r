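{
  "drug": {
    "name": "aripiprazole lauroxil",
    "mw_g_mol": 660.73, "logp": 9.8, "pka": 7.47,
    "rbp": 0.64, "fup": 0.002,
    "s_ref_mg_ml": 3e-04, "ph_ref": 7, "solubility_factor": 10200
  },
  "parent": {
    "name": "aripiprazole",
    "mw_g_mol": 448.38, "logp": 5.2, "pka": 7.6,
    "rbp": 0.61, "fup": 0.0317,
    "s_ref_mg_ml": 0.004, "ph_ref": 7, "solubility_factor": 660.92
  },
  "dose": {
    "ar_equivalent_dose_mg": 300, "route": "im_suspension",
    "is_prodrug": true, "injection_volume_ml": 1.6
  },
  "disposition": {
    "vc_l_kg": 1.5825, "clh_l_h_kg": 0.03028,
    "k12_1_h": 0.22832, "k21_1_h": 0.17345,
    "k13_1_h": 0.01108, "k31_1_h": 0.001911,
    "body_weight_kg": 70
  },
  "depot": {
    "kp": 4.28, "fut": 2.25e-08, "perfusion_ml_min_100g": 9.6,
    "ecf_fraction": 0.118
  },
  "psd": {
    "mean_radius_um": 14.18, "sd_radius_um": 7.4,
    "n_bins": 20, "density_g_cm3": 1.774
  },
  "dissolution": { "h_uwl_um": 65, "h_rule": "constant" },
  "icl": {
    "A_cm_h": 2.09e-06, "B_1_h": 0.012, "t_lag_h": 0,
    "kappa": 1, "enabled": true
  },
  "horizon_h": 2136
}
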