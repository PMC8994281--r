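{
  "A_carlinii": "Echinophthiriidae",
  "A_lobodontis": "Echinophthiriidae",
  "A_microchir": "Echinophthiriidae",
  "P_fluctus": "Echinophthiriidae",
  "L_macrorhini": "Echinophthiriidae",
  "Echinophthiriidae_MRCA": "Echinophthiriidae",
  "P_pubis": "Pthiridae",
  "P_gorillae": "Pthiridae",
  "P_obtusus": "Pedicinidae",
  "Primate_MRCA": "Pthiridae",
  "H_apri": "Haematopinidae"
}
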