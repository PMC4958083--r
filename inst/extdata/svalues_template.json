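{
  "_comment": "SYNTHETIC template. Placeholder S values on the mGy/(MBq h) scale; substitute values from MIRD-schema software (e.g. OLINDA/EXM) for the radionuclide and reference anatomy before any real analysis.",
  "s_mGy_per_MBq_h": {
    "RM<-RM": 0.003,
    "RM<-RB": 0.0005
  },
  "reference_rm_volume_mL": 1120,
  "reference_body_weight_kg": 73.7
}
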