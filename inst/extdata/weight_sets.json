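{
  "coords_only": {"cablam_outliers": 0.5, "calpha_outliers": 0.3, "clashscore": 0.2},
  "fit_to_map": {"emringer": 0.3, "qscore": 0.3, "atom_inclusion": 0.2, "smoc": 0.2},
  "vs_reference": {"lddt": 0.9, "gdc_all": 0.9, "hbpr_gt6": 0.2}
}
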