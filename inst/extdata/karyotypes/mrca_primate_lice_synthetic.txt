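#taxon MRCA_primate_lice
#missing N
#source synthetic reconstruction of the higher-primate louse ancestor: the sucking-louse MRCA after the primate-lineage splits (cox2 from nad6, nad4L from cox3-A, nad1 from nad3), retaining cox3-A and separate cox2 / nad2 minichromosomes as required by the published merger statements
atp8-atp6
C
S1-S2-E-cob
M-I-cox1-L2
Y-cox2
cox3-A
K-nad4
F-T-D-H-R-nad4L
Q-nad1-G
W-nad2
nad3
P-nad5
nad6
L1-rrnS
V-rrnL
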