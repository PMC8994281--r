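#taxon H_apri
#source synthetic reconstruction of the wild pig louse (family Haematopinidae), 9 minichromosomes: the sucking-louse MRCA arrangement with the two published mergers applied (atp8-atp6-N with K-nad4; I-cox1-L2 with nad2)
atp8-atp6-N-K-nad4
S1-S2-E-cob
D-Y-cox2-nad6
M-I-cox1-L2-C-nad2
R-nad4L-P-cox3-A
Q!-nad1!-T*!-G-nad3-W
F-H-nad5
L1-rrnS
V-rrnL
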