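mirna	target_gene	location	I	II	III	IV	annotation	other_evidence	race
miR2275	GRMZM2G044004	3'-UTR	0.33 (4)				nucleic acid binding protein	N	N
miR2275	GRMZM2G154532	5'-UTR/CDS				0.57 (2)	NAD dependent epimerase/dehydratase family protein	N	N
miR2275	GRMZM2G329532	CDS				1.00 (1)	unknown	N	N
miR2118	GRMZM2G066406	5'-UTR			16.00 (1)	2.00 (1)	unknown	N	N
miR2118	GRMZM2G031788	CDS				2.00 (1)	unknown	N	N
miRs4	GRMZM2G078124	CDS/3'-UTR		1.00 (2)			Molluscan rhodopsin C-terminal tail	N	N
miRs4	GRMZM5G829103	3'-UTR		1923.40 (0)			CCAAT-binding transcription factor	B26,B28	N
miRs4	GRMZM2G165488	3'-UTR		2804.25 (0)			CCAAT-binding transcription factor	B26,B28	N
miRs4	GRMZM2G000686	3'-UTR		21.80 (0)			CCAAT-binding transcription factor	B26,B28	N
miRs9	GRMZM2G467356	CDS				12.00 (0)	Ferredoxin	N	N
miRs14	GRMZM2G079683	3'-UTR	1.00 (4)				unknown	N	N
miRs15	GRMZM2G091189	3'-UTR		0.33 (4)			transcription factor	N	N
miRs17	GRMZM2G160041	CDS	0.25 (4)			1.75 (0)	DNA binding protein	N	N
miRs17	GRMZM2G085550	3'-UTR			5.00 (1)		unknown	N	N
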