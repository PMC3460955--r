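gene_name	symbol	cytoband	r_squared	not_amplified_or_deleted
Cold shock domain containing E1, RNA-binding	CSDE1	1p22	0.93	FALSE
Transcription termination factor, RNA polymerase II	TTF2	1p22	0.75	FALSE
Breast carcinoma amplified sequence 2	BCAS2	1p21-p13.3	0.90	FALSE
Amylase, alpha 2B (pancreatic)	AMY2B	1p21	0.71	FALSE
Tryptophanyl tRNA synthetase 2, mitochondrial	WARS2	1p13.3-p13.1	0.85	FALSE
Synaptotagmin VI	SYT6	1p13.2	0.78	FALSE
Mannosidase, alpha, class 1A, member 2	MAN1A2	1p13	0.89	FALSE
Adenosine monophosphate deaminase 1 (isoform M)	AMPD1	1p13	0.83	FALSE
Immunoglobulin superfamily, member 3	IGSF3	1p13	0.76	FALSE
Zinc finger protein 697	ZNF697	1p12	0.82	FALSE
Signal recognition particle 72kDa	SRP72	4q11	0.77	FALSE
Transmembrane protein 165	TMEM165	4q12	0.92	FALSE
FIP1 like 1 (S. cerevisiae)	FIP1L1	4q12	0.92	FALSE
Exocyst complex component 1	EXOC1	4q12	0.90	FALSE
Clock homolog (mouse)	CLOCK	4q12	0.88	FALSE
Polymerase (RNA) II (DNA directed) polypeptide B	POLR2B	4q12	0.87	FALSE
Steroid 5 alpha-reductase 3	SRD5A3	4q12	0.77	FALSE
DCN1, defective in cullin neddylation 1, domain containing 4	DCUN1D4	4q12	0.75	FALSE
Chromosome 4 open reading frame 14	C4orf14	4q12	0.74	FALSE
Sec1 family domain containing 2	SCFD2	4q12	0.71	FALSE
Transmembrane protein 106B	TMEM106B	7p21.3	0.84	FALSE
Epidermal growth factor receptor	EGFR	7p12	0.85	FALSE
Peroxisome biogenesis factor 1	PEX1	7q21.2	0.79	FALSE
GATA zinc finger domain containing 1	GATAD1	7q21-q22	0.78	FALSE
Methylthioadenosine phosphorylase	MTAP	9p21	0.73	FALSE
Eukaryotic translation initiation factor 3, subunit M	EIF3M	11p13	0.78	FALSE
IMP1 inner mitochondrial membrane peptidase-like	IMMP1L	11p13	0.75	TRUE
Amplified in osteosarcoma	OS9	12q13	0.86	FALSE
Methyltransferase like 1	METTL1	12q13	0.82	FALSE
Solute carrier family 16, member 7	SLC16A7	12q13	0.78	FALSE
Cytochrome P450, family 27, subfamily B, polypeptide 1	CYP27B1	12q13.1-q13.3	0.87	FALSE
Phosphatidylinositol-5-phosphate 4-kinase, type II, gamma	PIP4K2C	12q13.3	0.90	FALSE
Deltex 3 homolog (Drosophila)	DTX3	12q13.3	0.75	FALSE
Beta-1,4-N-acetyl-galactosaminyl transferase 1	B4GALNT1	12q13.3	0.72	FALSE
Methyl-CpG binding domain protein 6	MBD6	12q13.3	0.75	FALSE
Ts translation elongation factor, mitochondrial	TSFM	12q13-q14	0.87	FALSE
Carboxy-terminal domain small phosphatase 2	CTDSP2	12q13-q15	0.91	FALSE
RAP1B, member of RAS oncogene family	RAP1B	12q14	0.97	FALSE
Cyclin-dependent kinase 4	CDK4	12q14	0.81	FALSE
Family with sequence similarity 119, member B	FAM119B	12q14.1	0.80	FALSE
Advillin	AVIL	12q14.1	0.78	FALSE
Glutamate receptor interacting protein 1	GRIP1	12q14.3	0.95	FALSE
Mdm2, transformed 3T3 cell double minute 2	MDM2	12q14.3-q15	0.96	FALSE
Nucleoporin 107kDa	NUP107	12q15	0.85	FALSE
Solute carrier family 35, member E3	SLC35E3	12q15	0.79	FALSE
X (inactive)-specific transcript	XIST	Xq13.2	0.96	TRUE
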