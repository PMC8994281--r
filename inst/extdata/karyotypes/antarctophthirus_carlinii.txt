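#taxon A_carlinii
#missing nad6 C D F M S1 V
#source Weddell seal louse; 9 minichromosomes, 30 of 37 genes identified; karyotype identical to A_lobodontis; Q-nad1-T reverse-oriented; multi-anchor placements are a synthetic reconstruction (the published per-minichromosome text is internally inconsistent with the printed counts)
atp8-atp6-N
E-cob-rrnL
I-cox1-L2
L1-W-cox2
P-cox3-A
K-nad4-H-nad5
S2-Q!-nad1!-T!
G-R-nad4L
Y-nad2-nad3-rrnS
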