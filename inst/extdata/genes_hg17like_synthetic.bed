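chr1	202599999	202640000	MDM4
chr1	202699999	202770000	PIK3C2B
chr1	202849999	202880000	SOX13
chr1	202899999	202912000	REN
chr1	202969999	202976000	KISS1
chr4	54299999	54390000	LNX1
chr4	54599999	54680000	FIP1L1
chr4	54679999	54720000	CHIC2
chr4	54789999	54860000	PDGFRA
chr4	54899999	55050000	SCFD2
chr4	55149999	55200000	POLR2B
chr4	55249999	55280000	SRD5A3
chr4	55399999	55520000	CLOCK
chr4	55599999	55680000	EXOC1
chr4	55799999	55860000	TMEM165
chr7	54569999	54610000	VSTM2A
chr7	55053999	55242000	EGFR
chr7	55379999	55430000	LANCL2
chr7	55449999	55580000	VOPP1
chr9	21154999	21156000	IFNA4
chr9	21195999	21197000	IFNA7
chr9	21216999	21218000	IFNA17
chr9	21339999	21345000	KLHL9
chr9	21802634	21867763	MTAP
chr9	21957750	21984490	CDKN2A
chr9	21992901	21999312	CDKN2B
chr9	23689999	23830000	ELAVL2
chr9	25669999	25680000	TUSC1
chr10	89499999	89550000	ATAD1
chr10	89613174	89718512	PTEN
chr10	90419999	90460000	LIPA
chr10	90739999	90770000	FAS
chr11	31389999	31410000	IMMP1L
chr11	32569999	32610000	EIF3M
chr12	56099999	56130000	OS9
chr12	56199999	56210000	B4GALNT1
chr12	56379999	56390000	CDK4
chr12	56439999	56450000	CYP27B1
chr12	56529999	56540000	METTL1
chr12	56599999	56620000	AVIL
chr12	56749999	56780000	TSFM
chr12	56799999	56820000	FAM119B
chr12	56999999	57050000	RAP1B
chr12	57199999	57250000	NUP107
chr12	57299999	57600000	GRIP1
chr12	57799999	57840000	MDM2
chr12	57899999	57920000	SLC35E3
chr12	57999999	58100000	CPM
chr17	57099999	57180000	GRB2
chr17	57999999	58200000	ICAM2
chrX	72899999	73000000	XIST
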