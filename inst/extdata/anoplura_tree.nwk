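(((((A_carlinii:0.02,A_lobodontis:0.02)CarLob:0.10,A_microchir:0.25)Antarctophthirus:0.10,P_fluctus:0.30)AntPro:0.10,L_macrorhini:0.40)Echinophthiriidae_MRCA:0.30,(((P_pubis:0.10,P_gorillae:0.10)Pthirus:0.20,P_obtusus:0.30)Primate_MRCA:0.15,H_apri:0.40)PrimHaem:0.10)Anoplura_MRCA;
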