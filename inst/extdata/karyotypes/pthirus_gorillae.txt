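#taxon P_gorillae
#missing N
#source gorilla louse; 17 minichromosomes, 36 of 37 genes identified; atp8-atp6 carries no tRNA; trnA and trnC occupy their own minichromosomes; cox3 split from the ancestral cox3-A; F-T-D-H-R-nad4L as published; all genes share one transcription orientation; remaining placements and the tRNA-only G-Y minichromosome are a synthetic reconstruction
atp8-atp6
A
C
S1-S2-E-cob
M-I-cox1-L2
cox2
cox3
K-nad4
F-T-D-H-R-nad4L
Q-nad1
W-nad2
nad3
P-nad5
L1-nad6
rrnS
V-rrnL
G-Y
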