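marker	forward	reverse	amplicon_bp	ta_optimum
psbK-psbI	TTAGCATTTGTTTGGCAAG	AAAGTTTGAGAGTAAGCAT	544	51
trnH-psbA	GTTATGCACGAACGTAATGCTC	CGCGCGTGGTGGATTCACAATCC	300	55
matK	CGTACTGTACTTTTATGTTTACGAG	ATCCGGTCCATCTAGAAATATTGGTTC	862	55
atpF-atpH	ACTCGCACACACTCCCTTTCC	GCTTTTATGGAAGCTTTAACAAT	675	53
rpoB	ATGCAGCGTCAAGCAGTTCC	TCGGATGTGAAAAGAAGTATA	406	55
rpoC1	GGAAAAGAGGGAAGATTCCG	CAATTAGCATATCTTGAGTTGG	509	56
rbcL	GTAAAATCAAGTCCACCACG	ATGTCACCACAAACAGAGACTAAAGC	580	56
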