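gene_locus	categories
cpaE	Pilus
cpaF	Pilus
cpaD	Pilus
maf	Cell division
ftsK	Cell division
ftsH	Cell division
ftsY	Cell division
ftsE	Cell division
ftsI	Cell division
ftsW	Cell division
mraZ	Cell division
hdaA	Cell cycle
dnaA	Cell cycle
divJ	Cell cycle
divL	Cell cycle
cpdR	Cell cycle
podJ	Cell cycle
tipN	Cell cycle
cenR	Cell cycle
chpT	Cell cycle
kidO	Cell cycle
tacA	Cell cycle
pleD	Cell cycle
cckA	Cell cycle
popZ	Cell cycle
mipZ	Chromosome partitioning
parA	Chromosome partitioning
spoT	ppGpp
shkA	Stalk
fliF	Flagellum
flgE	Flagellum
fljK	Flagellum
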