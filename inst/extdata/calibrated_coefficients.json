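{
  "ir_activation": 1.0,
  "pip2_phosphorylation": 1.0,
  "akt_activation_pdk1": 1.0,
  "akt_activation_mtorc2": 1.0,
  "s6k_activation": 1.0,
  "glut4_mobilization_stim": 1.0,
  "glut4_translocation_stim": 1.0
}
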