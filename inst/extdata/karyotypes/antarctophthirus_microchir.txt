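#taxon A_microchir
#missing nad4L nad6 A C E F G H L1 L2 M N Q R S1 S2 V
#source Australian sea lion louse; 12 minichromosomes, 20 of 37 genes identified; atp8-atp6-D is the only multi-protein minichromosome; tRNA placements not fixed by the published text are reconstructed
atp8-atp6-D
cob
I-cox1
cox2
P-cox3
K-nad4
nad1!-T!
Y-nad5
nad3
W-nad2
rrnS
rrnL
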