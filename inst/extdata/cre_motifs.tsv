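name	iupac	note
CBF1/CRT	TGGCCGAC	dehydration/low-temperature responsive
AtHB5	CAATNATTG	homeodomain binding site
SURE1STPAT21	AATAGAAAA	sucrose responsive element
SURE2STPAT21	AATACAAAA	sucrose responsive element, alternative spelling
ABRE	ACGTGTC	abscisic acid responsive (also reported as ABR)
RAV1-B	CACCTG	RAV1 binding site B
MYCATERD22	CACATG	MYC recognition, dehydration responsive
WBBOXPCWRKY1	TTTGACY	W-box, pathogen/elicitor responsive
GT1GMSCAM4	GAAAAA	GT-1 motif, defensin promoters
MYCATERD1	CATGTG	MYC recognition, dehydration responsive
RAV1AAT	CAACA	RAV1 binding site A, defensin promoters
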