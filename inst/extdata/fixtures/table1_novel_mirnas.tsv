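mirna	sequence	ori	size_nt	loci	mirna_abundance	star_seq	star_abundance	precursor_location
zma-miRs1a	GGUGAACCACCGGACAUCGCAC	5'	22	1	13	NO	0	Chr10:170455..170536:-
zma-miRs1b	GGUGAACCACCGGACAUCGCAC	3'	22	1	21	NO	0	Chr1:261835708..261835791:-
zma-miRs2	UUUGACCAAGUUUGUAGAAAA	5'	21	1	10	NO	0	Chr10:7112184..7112314:-
zma-miRs3	UAUACACUGUGGUUGUGGAUG	5'	21	1	64	NO	0	Chr10:140401501..140401631:-
zma-miRs4	UAGCCAAGCAUGAUUUGCCCGU	5'	22	1	7	NO	0	Chr1:297173995..297174083:+
zma-miRs5	UGAUGCCAUUCAUUAAUCUC	5'	20	3	16	NO	0	Chr1:16908651..16908718:-
zma-miRs6a	UGGGUCAAGAAAGUAGAUGAAG	5'	22	6	4439	UCAUGUAUUUCUUCAUCCAGG	6	Chr1:145766064..145766151:-
zma-miRs6b	UGGGUCAAGAAAGUAGAUGAAG	5'	22	2	4314	UCAUGUAUUUCUUCAUCCAGG	6	Chr8:65126597..65126681:+
zma-miRs7	UUGGAGGGGAUUGAGGGGGCUA	5'	22	1	13	NO	0	Chr2:160587100..160587178:-
zma-miRs8	UUGGAUUGGUUUAGAGUGGUU	5'	21	3	9	NO	0	Chr2:193765038..193765121:-
zma-miRs9	UUAGGCUCGGGGACUAUGGUG	5'	21	1	56	CCGUGGCUCCUGCUCCUGAUG	1	Chr3:37277918..37278069:+
zma-miRs10	AUCGGCUGAUCGUUUGGCCUG	5'	21	1	12	NO	0	Chr3:95960134..95960203:+
zma-miRs11	CGUGGAACUUCUUCGGCGUAG	5'	21	1	59	GUGCCGAAGAAGAACUUCCUGCA	2	Chr4:6987996..6988075:-
zma-miRs12	UGGCUGUGAUGACAAAAAGGU	5'	21	1	14	NO	0	Chr5:13726506..13726621:+
zma-miRs13	UGAGUUUAGGGACUGGGAUGG	3'	21	1	5	NO	0	Chr5:33732172..33732274:+
zma-miRs14	UGAAACUGUCACAGCAUGAUC	5'	21	1	6	NO	0	Chr5:7648838..7648949:-
zma-miRs15	UGUUCGGUUGCUCAGGAACGGU	5'	22	1	9	NO	0	Chr6:102874227..102874366:+
zma-miRs16	UUGCCAGGAGGAGGAUGGAGC	3'	21	1	65	NO	0	Chr9:7189032..7189100:+
zma-miRs17	UGAAAAGCUAGAACGAUUUAC	3'	21	1	9	NO	0	Chr9:33858898..33859002:-
zma-miRs18	GUACUACGGGUACUGCGAGC	3'	20	1	5	NO	0	Chr1:140132808..140132921:+
zma-miRs19a	UGGUUGACAUAUGGACCCCAC	5'	21	1	5	NO	0	Chr2:196666638..196666791:+
zma-miRs19b	UGGUUGACAUAUGGACCCCAC	5'	21	1	5	NO	0	Chr2:196666638..196666790:-
zma-miRs19c	UGGUUGACAUAUGGACCCCAC	5'	21	1	5	NO	0	Chr5:182646213..182646347:+
zma-miRs19d	UGGUUGACAUAUGGACCCCAC	5'	21	1	5	NO	0	Chr9:114976246..114976391:-
zma-miRs20	AGGGCUUGUUCGUUUUGGAGU	5'	21	1	35	NO	0	Chr4:41972777..41972854:-
zma-miRs21	GGUGUUGGUGCCUGUAGCGG	5'	20	1	7	NO	0	Chr7:6041852..6041939:+
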