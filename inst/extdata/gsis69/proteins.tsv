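abbrev	protein_name	swissprot_id	pathways	phylo_class	hm_similarity
GK	Glucokinase	P35557	G	U	98.3
F6P	6-phosphofructokinase	P17858	G	U	97.0
FBa	fructose-bisphosphate aldolase (A)	P04075	G	U	98.9
FBb	fructose-bisphosphate aldolase (B)	P05062	G	U	99.7
FBc	fructose-bisphosphate aldolase (C)	P09972	G	U	98.6
GAPD	glyceraldehyde 3-phosphate dehydrogenase	P04406	G	U	97.0
PGP1	bisphosphoglycerate phosphatase (1)	P18669	G	U	99.6
PGP2	bisphosphoglycerate phosphatase (2)	P15259	G	U	95.2
PK	Pyruvate kinase	P30613	G	U	95.5
LDHa	Lactate dehydrogenase A	P00338	G	U	97.6
LDHb	Lactate dehydrogenase B	P07195	G	U	99.1
PDCa	Pyruvate Dehydrogenase Complex A	P08559	T	U	99.5
PDCb	Pyruvate Dehydrogenase Complex B	P11177	T	U	97.5
PDCc	Pyruvate Dehydrogenase Complex C	P29803	T	U	87.2
CS	Citrate Synthase	O75390	T,P	U	97.4
ACO	Aconitase	Q99798	T,P	U	98.8
IDHa	Isocitrate Dehydrogenase (NAD+) (A)	P50213	T,P	U	98.6
IDHg	Isocitrate Dehydrogenase (NAD+) (G)	P51553	T,P	U	97.2
OGDC	Oxoglutarate Dehydrogenase Complex	Q02218	T	U	94.1
SCSa	Succinyl-CoA synthetase A	P53597	T	U	97.0
SCSb	Succinyl-CoA synthetase B	Q96I99	T	U	96.1
SDHa	Succinate Dehydrogenase A	P31040	T	U	94.0
SDHb	Succinate Dehydrogenase B	P21912	T	U	97.0
FM	Fumarase	P07954	T,N	U	95.3
MDH	Malate Dehydrogenase (mitochondrion & cytosol)	P40926	T,N	U	97.6
AlaTA	Alanine Transaminase	P24298	N	U	92.5
AspTA	Aspartate Transaminase	P00505	N	U	98.4
NDK	Nucleoside Diphosphate Kinase	O00746	T	U	87.8
MT-ND1	NADH: Ubiquinone oxidoreductase 1	O15239	R	E	92.9
MT-ND2	NADH: Ubiquinone oxidoreductase 2	O43678	R	E	93.9
MT-ND3	NADH: Ubiquinone oxidoreductase 3	O95167	R	E	88.1
MT-ND4	NADH: Ubiquinone oxidoreductase 4	O00483	R	E	92.7
MT-ND5	NADH: Ubiquinone oxidoreductase 5	Q16718	R	U	91.3
MT-ND6	NADH: Ubiquinone oxidoreductase 6	P56556	R	U	90.8
MT-ND7	NADH: Ubiquinone oxidoreductase 7	O95182	R	E	95.5
MT-ND8	NADH: Ubiquinone oxidoreductase 8	P51970	R	U	94.7
MT-ND9	NADH: Ubiquinone oxidoreductase 9	Q16795	R	U	87.3
UQCRH	Ubiquinol: Cytochrome c Oxidoreductase H	P08574	R	U	92.3
UQCRI	Ubiquinol: Cytochrome c Oxidoreductase I	P47985	R	U	94.5
UQCRQ	Ubiquinol: Cytochrome c Oxidoreductase Q	O14949	R	E	85.2
UQCRR1	Ubiquinol: Cytochrome c Oxidoreductase R1	O14957	R	M	92.7
UQCRC2	Ubiquinol: Cytochrome c Oxidoreductase C2	P22695	R	U	93.2
Cox6B1	Cytochrome c Oxidase 6B1	P14854	R	E	96.5
Cox2	Cytochrome c Oxidase 2 (mt-encoded)	P00403	R	U	86.8
Cox8a	Cytochrome c Oxidase 8a	P10176	R	V	85.5
Cox5a	Cytochrome c Oxidase 5A	P20674	R	U	88.0
Cox4a	Cytochrome c Oxidase 4A	P13073	R	E	89.9
Cox6c	Cytochrome c Oxidase 6C	P09669	R	M	86.7
Cox7b	Cytochrome c Oxidase 7B	P24311	R	V	88.8
Cox1	Cytochrome c Oxidase 1 (mt-encoded)	P00395	R	U	95.5
Cox7r	Cytochrome c Oxidase 7R	O14548	R	E	93.0
Cox7c	Cytochrome c Oxidase 7C	P15954	R	E	88.9
OGC	Oxoglutarate Carrier	Q02978	N,P	E	97.8
CIC	Citrate Carrier	P53007	M	E	96.5
NNT	Nicotinamide nucleotide transhydrogenase	Q13423	S	U	96.2
GSSGR	Glutathione reductase	P00390	S	U	89.3
GSSGP	Glutathione peroxidase	P07203	S	U	90.6
GUT2P	Glycerol-3-phosphate dehydrogenase (FAD dependent)	P43304	N	U	97.0
G3PD	Glycerol-3-phosphate dehydrogenase (NAD+)	P21695	N	U	96.8
MEx	Malate Dehydrogenase (oxaloacetate-decarboxylating) (NADP+) X	P48163	P	U	94.9
MEn	Malate Dehydrogenase (oxaloacetate-decarboxylating) (NADP+) N	Q16798	P	U	96.4
AAC	ATP/ADP Carrier 2	P05141	M	U	99.3
IDHcp	cytosolic Isocitrate Dehydrogenase (NADP+) P	P48735	P	U	82.0
IDHcc	cytosolic Isocitrate Dehydrogenase (NADP+) C	O75874	P	U	97.8
PC	Pyruvate Carboxylase	P11498	T,P	U	98.6
ETF-QO	ETF:Q oxidoreductase	Q16134	N	U	95.8
SOD2c	Manganese-dependent superoxide dismutase 2 C	P00441	S	U	88.9
SOD2m	Manganese-dependent superoxide dismutase 2 M	P04179	S	U	91.9
SOD2e	Manganese-dependent superoxide dismutase 2 E	P08294	S	U	75.2
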