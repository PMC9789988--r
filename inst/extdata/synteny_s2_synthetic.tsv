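species	focal_gene	offset	symbol	strand
Loc	HIF1A	-10	RAB15	+
Loc	HIF1A	-9	GPX2	+
Loc	HIF1A	-8	WDHD1	+
Loc	HIF1A	-7	AKAP5	+
Loc	HIF1A	-6	MTHFD1	+
Loc	HIF1A	-5	ZBTB25	+
Loc	HIF1A	-4	HSPA2	+
Loc	HIF1A	-3	PRKCH	+
Loc	HIF1A	-2	SYT16	+
Loc	HIF1A	-1	SNAPC1	+
Loc	HIF1A	1	SOCS4	+
Loc	HIF1A	2	MAPK1IP1L	+
Loc	HIF1A	3	LGALS3	+
Loc	HIF1A	4	DLGAP5	+
Loc	HIF1A	5	FBXO34	+
Loc	HIF1A	6	ATG14	+
Loc	HIF1A	7	TBPL2	+
Loc	HIF1A	8	KTN1	+
Loc	HIF1A	9	PELI2	+
Loc	HIF1A	10	FNTB	+
Dre	HIF1Aa	-10	RAB15	+
Dre	HIF1Aa	-9	GPX2	+
Dre	HIF1Aa	-8	WDHD1	+
Dre	HIF1Aa	-7	AKAP5	+
Dre	HIF1Aa	-6	MTHFD1	+
Dre	HIF1Aa	-5	ZBTB25	+
Dre	HIF1Aa	-4	HSPA2	+
Dre	HIF1Aa	-3	PRKCH	+
Dre	HIF1Aa	-2	SYT16	+
Dre	HIF1Aa	-1	SNAPC1	+
Dre	HIF1Aa	1	SOCS4	+
Dre	HIF1Aa	2	KTN1	+
Dre	HIF1Aa	3	NOV101	+
Dre	HIF1Aa	4	FBXO34	+
Dre	HIF1Aa	5	NOV102	+
Dre	HIF1Aa	6	NOV103	+
Dre	HIF1Aa	7	ATG14	+
Dre	HIF1Aa	8	NOV104	+
Dre	HIF1Aa	9	NOV105	+
Dre	HIF1Aa	10	NOV106	+
Dre	HIF1Ab	-10	HSPA2	+
Dre	HIF1Ab	-9	NOV113	+
Dre	HIF1Ab	-8	SYT16	-
Dre	HIF1Ab	-7	NOV112	+
Dre	HIF1Ab	-6	AKAP5	-
Dre	HIF1Ab	-5	MTHFD1	+
Dre	HIF1Ab	-4	NOV111	+
Dre	HIF1Ab	-3	SNAPC1	-
Dre	HIF1Ab	-2	PRKCH	+
Dre	HIF1Ab	-1	GPX2	-
Dre	HIF1Ab	1	KTN1	+
Dre	HIF1Ab	2	NOV114	+
Dre	HIF1Ab	3	DLGAP5	+
Dre	HIF1Ab	4	SOCS4	+
Dre	HIF1Ab	5	NOV115	+
Dre	HIF1Ab	6	NOV116	+
Dre	HIF1Ab	7	unknown	+
Dre	HIF1Ab	8	NOV117	+
Dre	HIF1Ab	9	NOV118	+
Dre	HIF1Ab	10	NOV119	+
Loc	HIF2A	-10	KCNK12	+
Loc	HIF2A	-9	MSH2	+
Loc	HIF2A	-8	EPCAM	+
Loc	HIF2A	-7	CALM2	+
Loc	HIF2A	-6	TTC7A	+
Loc	HIF2A	-5	MCFD2	+
Loc	HIF2A	-4	SOCS5	+
Loc	HIF2A	-3	CRIPT	+
Loc	HIF2A	-2	PIGF	+
Loc	HIF2A	-1	RHOQ	+
Loc	HIF2A	1	TMEM247	+
Loc	HIF2A	2	ATP6V1E2	+
Loc	HIF2A	3	PROKR1	+
Loc	HIF2A	4	ARHGAP25	+
Loc	HIF2A	5	BCL11A	+
Loc	HIF2A	6	PAPOLG	+
Loc	HIF2A	7	REL	+
Loc	HIF2A	8	PUS10	+
Loc	HIF2A	9	PEX13	+
Loc	HIF2A	10	KIAA1841	+
Dre	HIF2A.chr13	-10	NOV203	+
Dre	HIF2A.chr13	-9	NOV202	+
Dre	HIF2A.chr13	-8	EPCAM	+
Dre	HIF2A.chr13	-7	CALM2	+
Dre	HIF2A.chr13	-6	NOV201	+
Dre	HIF2A.chr13	-5	MCFD2	+
Dre	HIF2A.chr13	-4	SOCS5	+
Dre	HIF2A.chr13	-3	CRIPT	+
Dre	HIF2A.chr13	-2	PIGF	+
Dre	HIF2A.chr13	-1	RHOQ	+
Dre	HIF2A.chr13	1	TMEM247	+
Dre	HIF2A.chr13	2	ATP6V1E2	+
Dre	HIF2A.chr13	3	PROKR1	+
Dre	HIF2A.chr13	4	NOV204	+
Dre	HIF2A.chr13	5	BCL11A	+
Dre	HIF2A.chr13	6	NOV205	+
Dre	HIF2A.chr13	7	REL	+
Dre	HIF2A.chr13	8	NOV206	+
Dre	HIF2A.chr13	9	NOV207	+
Dre	HIF2A.chr13	10	unknown	+
Dre	HIF2A.chr12	-10	KCNK12	+
Dre	HIF2A.chr12	-9	MSH2	+
Dre	HIF2A.chr12	-8	PFN4	+
Dre	HIF2A.chr12	-7	TP53I3	+
Dre	HIF2A.chr12	-6	SF3B6	+
Dre	HIF2A.chr12	-5	FAM228A	+
Dre	HIF2A.chr12	-4	TRIB2	+
Dre	HIF2A.chr12	-3	LPIN1	+
Dre	HIF2A.chr12	-2	NTSR2	+
Dre	HIF2A.chr12	-1	GREB1	+
Dre	HIF2A.chr12	1	ITSN2	+
Dre	HIF2A.chr12	2	NCOA1	+
Dre	HIF2A.chr12	3	CENPO	+
Dre	HIF2A.chr12	4	ADCY3	+
Dre	HIF2A.chr12	5	DNAJC27	+
Dre	HIF2A.chr12	6	POMC	+
Dre	HIF2A.chr12	7	DNMT3A	+
Dre	HIF2A.chr12	8	NOV211	+
Dre	HIF2A.chr12	9	NOV212	+
Dre	HIF2A.chr12	10	NOV213	+
Omy	HIF2Ab.trunc	-10	unknown	+
Omy	HIF2Ab.trunc	-9	NOV222	+
Omy	HIF2Ab.trunc	-8	NOV221	+
Omy	HIF2Ab.trunc	-7	TP53I3	+
Omy	HIF2Ab.trunc	-6	SF3B6	+
Omy	HIF2Ab.trunc	-5	FAM228A	+
Omy	HIF2Ab.trunc	-4	TRIB2	+
Omy	HIF2Ab.trunc	-3	LPIN1	+
Omy	HIF2Ab.trunc	-2	NTSR2	+
Omy	HIF2Ab.trunc	-1	GREB1	+
Omy	HIF2Ab.trunc	1	PFN4	+
Omy	HIF2Ab.trunc	2	ITSN2	+
Omy	HIF2Ab.trunc	3	NCOA1	+
Omy	HIF2Ab.trunc	4	CENPO	+
Omy	HIF2Ab.trunc	5	ADCY3	+
Omy	HIF2Ab.trunc	6	DNAJC27	+
Omy	HIF2Ab.trunc	7	POMC	+
Omy	HIF2Ab.trunc	8	DNMT3A	+
Omy	HIF2Ab.trunc	9	NOV223	+
Omy	HIF2Ab.trunc	10	NOV224	+
Loc	HIF3A	-10	MYBPC2	+
Loc	HIF3A	-9	SAE1	+
Loc	HIF3A	-8	ZC3H4	+
Loc	HIF3A	-7	TMEM160	+
Loc	HIF3A	-6	NPAS1	+
Loc	HIF3A	-5	IRF2BP1	+
Loc	HIF3A	-4	FOXA3	+
Loc	HIF3A	-3	SYMPK	+
Loc	HIF3A	-2	SELP	+
Loc	HIF3A	-1	BBC3	+
Loc	HIF3A	1	PNMA8A	+
Loc	HIF3A	2	SNRNP70	+
Loc	HIF3A	3	LIN7B	+
Loc	HIF3A	4	C5AR1	+
Loc	HIF3A	5	CCDC9	+
Loc	HIF3A	6	DHDH	+
Loc	HIF3A	7	BAX	+
Loc	HIF3A	8	FTL	+
Loc	HIF3A	9	GYS1	+
Loc	HIF3A	10	RUVBL2	+
Dre	HIF3A	-10	NOV307	+
Dre	HIF3A	-9	unknown	+
Dre	HIF3A	-8	NOV306	+
Dre	HIF3A	-7	NOV305	+
Dre	HIF3A	-6	NOV304	+
Dre	HIF3A	-5	NOV303	+
Dre	HIF3A	-4	FOXA3	+
Dre	HIF3A	-3	NOV302	+
Dre	HIF3A	-2	NOV301	+
Dre	HIF3A	-1	SYMPK	+
Dre	HIF3A	1	BAX	+
Dre	HIF3A	2	NOV308	+
Dre	HIF3A	3	NOV309	+
Dre	HIF3A	4	NOV310	+
Dre	HIF3A	5	NOV311	+
Dre	HIF3A	6	NOV312	+
Dre	HIF3A	7	NOV313	+
Dre	HIF3A	8	NOV314	+
Dre	HIF3A	9	NOV315	+
Dre	HIF3A	10	NOV316	+
Xma	HIF3A	-10	NOV324	+
Xma	HIF3A	-9	SAE1	+
Xma	HIF3A	-8	NOV323	+
Xma	HIF3A	-7	NOV322	+
Xma	HIF3A	-6	NPAS1	+
Xma	HIF3A	-5	NOV321	+
Xma	HIF3A	-4	FOXA3	+
Xma	HIF3A	-3	SYMPK	+
Xma	HIF3A	-2	SELP	+
Xma	HIF3A	-1	BBC3	+
Xma	HIF3A	1	PNMA8A	+
Xma	HIF3A	2	SNRNP70	+
Xma	HIF3A	3	NOV325	+
Xma	HIF3A	4	NOV326	+
Xma	HIF3A	5	BAX	+
Xma	HIF3A	6	NOV327	+
Xma	HIF3A	7	NOV328	+
Xma	HIF3A	8	NOV329	+
Xma	HIF3A	9	NOV330	+
Xma	HIF3A	10	NOV331	+
Eluc	HIF1Aa	-10	RAB15	+
Eluc	HIF1Aa	-9	GPX2	+
Eluc	HIF1Aa	-8	NOV402	+
Eluc	HIF1Aa	-7	AKAP5	+
Eluc	HIF1Aa	-6	MTHFD1	+
Eluc	HIF1Aa	-5	NOV401	+
Eluc	HIF1Aa	-4	HSPA2	+
Eluc	HIF1Aa	-3	PRKCH	+
Eluc	HIF1Aa	-2	SYT16	+
Eluc	HIF1Aa	-1	SNAPC1	+
Eluc	HIF1Aa	1	SOCS4	+
Eluc	HIF1Aa	2	MAPK1IP1L	+
Eluc	HIF1Aa	3	NOV403	+
Eluc	HIF1Aa	4	DLGAP5	+
Eluc	HIF1Aa	5	FBXO34	+
Eluc	HIF1Aa	6	NOV404	+
Eluc	HIF1Aa	7	TBPL2	+
Eluc	HIF1Aa	8	KTN1	+
Eluc	HIF1Aa	9	NOV405	+
Eluc	HIF1Aa	10	NOV406	+
Omy	HIF1Aa_s1	-10	NOV414	+
Omy	HIF1Aa_s1	-9	GPX2	+
Omy	HIF1Aa_s1	-8	NOV413	+
Omy	HIF1Aa_s1	-7	AKAP5	+
Omy	HIF1Aa_s1	-6	MTHFD1	+
Omy	HIF1Aa_s1	-5	NOV412	+
Omy	HIF1Aa_s1	-4	NOV411	+
Omy	HIF1Aa_s1	-3	PRKCH	+
Omy	HIF1Aa_s1	-2	SYT16	+
Omy	HIF1Aa_s1	-1	SNAPC1	+
Omy	HIF1Aa_s1	1	SOCS4	+
Omy	HIF1Aa_s1	2	NOV415	+
Omy	HIF1Aa_s1	3	NOV416	+
Omy	HIF1Aa_s1	4	DLGAP5	+
Omy	HIF1Aa_s1	5	NOV417	+
Omy	HIF1Aa_s1	6	NOV418	+
Omy	HIF1Aa_s1	7	TBPL2	+
Omy	HIF1Aa_s1	8	NOV419	+
Omy	HIF1Aa_s1	9	NOV420	+
Omy	HIF1Aa_s1	10	NOV421	+
Omy	HIF1Aa_s2	-10	NOV438	+
Omy	HIF1Aa_s2	-9	NOV437	+
Omy	HIF1Aa_s2	-8	NOV436	+
Omy	HIF1Aa_s2	-7	NOV435	+
Omy	HIF1Aa_s2	-6	MTHFD1	+
Omy	HIF1Aa_s2	-5	NOV434	+
Omy	HIF1Aa_s2	-4	NOV433	+
Omy	HIF1Aa_s2	-3	NOV432	+
Omy	HIF1Aa_s2	-2	NOV431	+
Omy	HIF1Aa_s2	-1	SNAPC1	+
Omy	HIF1Aa_s2	1	NOV439	+
Omy	HIF1Aa_s2	2	NOV440	+
Omy	HIF1Aa_s2	3	NOV441	+
Omy	HIF1Aa_s2	4	NOV442	+
Omy	HIF1Aa_s2	5	NOV443	+
Omy	HIF1Aa_s2	6	NOV444	+
Omy	HIF1Aa_s2	7	NOV445	+
Omy	HIF1Aa_s2	8	NOV446	+
Omy	HIF1Aa_s2	9	unknown	+
Omy	HIF1Aa_s2	10	NOV447	+
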