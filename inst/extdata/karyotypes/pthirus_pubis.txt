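#taxon P_pubis
#missing N
#source human pubic louse (prior work); 15 minichromosomes, trnN unidentified; retains the ancestral cox3-A minichromosome and trnL1 upstream of rrnS; placements beyond those statements are a synthetic reconstruction consistent with the P_gorillae comparison
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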