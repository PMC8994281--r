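#taxon L_macrorhini
#missing nad3 nad4L nad6 C F G R S1 S2 Y
#source southern elephant seal louse; 11 minichromosomes, 27 of 37 genes identified; trnW duplicated (W1, W2); Q, nad1, T* reverse-oriented; tRNA placements not fixed by the published text are reconstructed
atp8-atp6-N
E-cob
cox2
M-I-cox1-L2
P-cox3-A
K-nad4
Q!-nad1!-T*!-W1
H-nad5-W2
D-nad2
L1-rrnS
V-rrnL
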