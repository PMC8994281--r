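#taxon P_obtusus
#missing N
#source synthetic partial reconstruction of the macaque louse (family Pedicinidae): the primate-louse ancestor with the single published merger applied (the cox2 and nad2 minichromosomes fused); encodes the merger topology only, not the full published karyotype
atp8-atp6
C
S1-S2-E-cob
M-I-cox1-L2
Y-cox2-W-nad2
cox3-A
K-nad4
F-T-D-H-R-nad4L
Q-nad1-G
nad3
P-nad5
nad6
L1-rrnS
V-rrnL
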