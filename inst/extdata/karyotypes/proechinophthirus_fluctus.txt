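#taxon P_fluctus
#missing atp6 atp8 nad6 rrnL A D F L1 L2 M N P S1 V Y
#source northern fur seal louse; 10 minichromosomes, 22 of 37 genes identified; Q-nad1-T reverse-oriented; carries the nad4L+rrnS merger; tRNA placements not fixed by the published text are reconstructed
E-cob
G-cox2
I-cox1
C-cox3
K-nad4
Q!-nad1!-T!
H-nad5
S2-nad3
W-nad2
R-nad4L-rrnS
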