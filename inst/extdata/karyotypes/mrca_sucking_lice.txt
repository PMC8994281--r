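#taxon MRCA_sucking_lice
#source inferred most recent common ancestor of sucking lice (prior work); 11 minichromosomes carrying all 37 genes; consumed as an input fixture, never recomputed; minichromosomes not named in the text we transcribe from (F-H-nad5, C-nad2, L1-rrnS, V-rrnL) follow the arrangements conserved across louse families
atp8-atp6-N
S1-S2-E-cob
D-Y-cox2-nad6
M-I-cox1-L2
R-nad4L-P-cox3-A
K-nad4
Q!-nad1!-T*!-G-nad3-W
F-H-nad5
C-nad2
L1-rrnS
V-rrnL
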