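# Anthraquinone biosynthesis reference scheme: enzymes of the four feeder
# pathways (MVA, MEP, TCA cycle, shikimate) with KEGG Orthology ids and the
# unigene counts reported for the cultivated Rubia cordifolia full-length
# transcriptome.
pathway	ec	ko_id	gene_name	symbol	unigene_count
MVA	2.3.1.9	K00626	acetyl-CoA C-acetyltransferase	AACT	4
MVA	2.3.3.10	K01641	hydroxymethylglutaryl-CoA synthase	HMGS	2
MVA	1.1.1.34	K00021	hydroxymethylglutaryl-CoA reductase	HMGR	8
MVA	2.7.1.36	K00869	mevalonate kinase	MVK	3
MVA	2.7.4.2	K00938	phosphomevalonate kinase	PMK	2
MVA	4.1.1.33	K01597	diphosphomevalonate decarboxylase	MVD	3
MEP	2.2.1.7	K01662	1-deoxy-D-xylulose-5-phosphate synthase	DXS	13
MEP	1.1.1.267	K00099	1-deoxy-D-xylulose-5-phosphate reductoisomerase	DXR	10
MEP	2.7.7.60	K00991	2-C-methyl-D-erythritol 4-phosphate cytidylyltransferase	ispD/MCT	1
MEP	2.7.1.148	K00919	4-diphosphocytidyl-2-C-methyl-D-erythritol kinase	ispE/CMK	2
MEP	4.6.1.12	K01770	2-C-methyl-D-erythritol 2,4-cyclodiphosphate synthase	ispF/MDS	2
MEP	1.17.7.1/1.17.7.3	K03526	(E)-4-hydroxy-3-methylbut-2-enyl-diphosphate synthase	ispG/HDS	3
MEP	1.17.7.4	K03527	4-hydroxy-3-methylbut-2-en-1-yl diphosphate reductase	ispH/HDR	9
MEP	5.3.3.2	K01823	isopentenyl-diphosphate Delta-isomerase	IDI	4
TCA	1.1.1.37	K00026	malate dehydrogenase	MDH2	17
TCA	2.3.3.1	K01647	citrate synthase	CS/gltA	10
TCA	2.3.3.8	K01648	ATP citrate (pro-S)-lyase	ACLY	16
TCA	4.2.1.3	K01681	aconitate hydratase	ACO/acnA	12
TCA	1.1.1.42	K00031	isocitrate dehydrogenase	IDH1/icd	15
TCA	1.1.1.41	K00030	isocitrate dehydrogenase (NAD+)	IDH3	11
TCA	1.2.4.2	K00164	2-oxoglutarate dehydrogenase E1 component	OGDH/sucA	5
TCA	1.8.1.4	K00382	dihydrolipoyl dehydrogenase	DLD/lpd/pdhD	5
TCA	2.3.1.61	K00658	2-oxoglutarate dehydrogenase E2 component	DLST/sucB	7
TCA	6.2.1.4/6.2.1.5	K01899	succinyl-CoA synthetase alpha subunit	LSC1	2
TCA	6.2.1.4/6.2.1.5	K01900	succinyl-CoA synthetase beta subunit	LSC2	2
TCA	1.3.5.1	K00234	succinate dehydrogenase (ubiquinone) flavoprotein subunit	SDHA/SDH1	18
TCA	1.3.5.1	K00236	succinate dehydrogenase (ubiquinone) cytochrome b560 subunit	SDHC/SDH3	5
TCA	1.3.5.1	K00235	succinate dehydrogenase (ubiquinone) iron-sulfur subunit	SDHB/SDH2	4
TCA	4.2.1.2	K01679	fumarate hydratase, class II	fumC/FH	9
shikimate	2.5.1.54	K01626	3-deoxy-7-phosphoheptulonate synthase	aroF/aroG/aroH	13
shikimate	4.2.3.4	K01735	3-dehydroquinate synthase	aroB	3
shikimate	4.2.1.10/1.1.1.25	K13832	3-dehydroquinate dehydratase / shikimate dehydrogenase	aroDE/DHQ-SDH	13
shikimate	2.7.1.71	K00891	shikimate kinase	aroK/aroL	8
shikimate	2.5.1.19	K00800	3-phosphoshikimate 1-carboxyvinyltransferase	aroA	5
shikimate	4.2.3.5	K01736	chorismate synthase	aroC	5
shikimate	5.4.4.2	K02552	menaquinone-specific isochorismate synthase	menF	2
shikimate	5.4.4.2/2.2.1.9/4.2.99.20/4.2.1.113	K14759	isochorismate synthase / SEPHCHC synthase / SHCHC synthase / o-succinylbenzoate synthase	menC/D/H	8
shikimate	6.2.1.26	K14760	o-succinylbenzoate-CoA ligase	menE	7
shikimate	4.1.3.36	K01661	naphthoate synthase	menB	8
shikimate	3.1.2.28	K19222	1,4-dihydroxy-2-naphthoyl-CoA hydrolase	menI/DHNAT	4
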