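# Curated betabaculovirus core-gene reference: the 37 genes conserved across
# the Baculoviridae, assembled from the consensus core-gene inventory of the
# family literature. Aliases are pipe-separated; categories follow the usual
# functional grouping (replication, transcription, packaging/assembly,
# oral infectivity, release).
gene	aliases	category
lef-1	lef1	replication
lef-2	lef2	replication
dnapol	dna-pol|dna polymerase	replication
helicase	dnahel|p143	replication
alk-exo	an|alkaline exonuclease	replication
lef-4	lef4	transcription
lef-5	lef5	transcription
lef-8	lef8	transcription
lef-9	lef9	transcription
p47	ac40	transcription
vlf-1	vlf1	transcription
p74	pif-0|pif0	oral infectivity
pif-1	pif1	oral infectivity
pif-2	pif2	oral infectivity
pif-3	pif3	oral infectivity
pif-4	pif4|odv-28|19kda	oral infectivity
pif-5	pif5|odv-e56	oral infectivity
pif-6	pif6|ac68	oral infectivity
pif-7	pif7|ac110	oral infectivity
vp91	pif-8|pif8|p95	oral infectivity
p6.9	p6.9 basic protein	packaging/assembly
vp39	ac89	packaging/assembly
vp1054	ac54	packaging/assembly
gp41	ac80	packaging/assembly
38k	ac98	packaging/assembly
ac53	ac53-like	packaging/assembly
ac66	desmoplakin-like	packaging/assembly
ac78	ac78-like	packaging/assembly
ac81	ac81-like	packaging/assembly
p33	ac92|sulfhydryl oxidase	packaging/assembly
p18	ac93	packaging/assembly
p48	ac103	packaging/assembly
odv-ec43	ac109	packaging/assembly
p49	ac142	packaging/assembly
odv-e18	ac143	packaging/assembly
odv-ec27	ac144	packaging/assembly
ac132	ac132-like	packaging/assembly
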