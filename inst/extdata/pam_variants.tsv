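hgvs_c	hgvs_p	snp_id	location_gene	location_protein	variant_class	consequence	cohort_maf_pct	control_maf_pct	highest_pop_maf_pct	n_homozygotes_controls	printed_p	in_silico_prediction	printed_classification	verdict_pathogenic	verdict_uncertain	verdict_benign	plurality_classification	splice_or_regulatory_effect	published_functional_evidence
c.-607A>G	NA	rs76396377	promoter	NA	regulatory	utr	0.4	1.479	2.943	24	n.s.	1 TF replaced	NA	NA	NA	NA	NA	TRUE	FALSE
c.-550G>T	NA	rs1007572715	promoter	NA	regulatory	utr	0.4	0.0072	0.0415	0	<0.05	2 TFs lost	NA	NA	NA	NA	NA	TRUE	FALSE
c.-361G>A	NA	rs143617515	5'UTR (exon 1)	NA	regulatory	utr	1.21	0.6275	3.647	12	n.s.	2 TFs lost, 4 TFs created	NA	NA	NA	NA	NA	TRUE	FALSE
c.-133T>C	NA	rs1413721196	5'UTR (exon 1)	NA	regulatory	utr	0.25	0.0007	0.0015	0	<0.05	1 TF lost	NA	NA	NA	NA	NA	TRUE	FALSE
c.-109G>C	NA	Novel	5'UTR (exon 1)	NA	regulatory	utr	0.25	NA	NA	NA	n.a.	1 TF replaced	NA	NA	NA	NA	NA	TRUE	FALSE
c.-35C>G	NA	rs201016377	5'UTR (exon 1)	NA	regulatory	utr	0.15	0.0749	0.9040	1	n.s.	n.a.	NA	NA	NA	NA	NA	FALSE	FALSE
c.79G>A	p.Val27Ile	rs199856250	exon 1	proregion	coding	missense	0.16	0.0004	0.0008	0	<0.05	VUS (1, 6, 12)	vus	1	6	12	likely_benign	FALSE	FALSE
c.92T>A	p.Phe31Tyr	rs114014768	exon 2	linker region	coding	missense	0.63	0.8654	2.814	19	n.s.	likely benign (0, 1, 16)	likely_benign	0	1	16	likely_benign	FALSE	FALSE
c.145G>C	p.Val49Leu	rs2230458	exon 2	PHMcc	coding	missense	0.94	0.9278	1.803	5	n.s.	likely benign (0, 2, 17)	likely_benign	0	2	17	likely_benign	FALSE	FALSE
c.239G>A	p.Arg80Gln	rs753307443	exon 3	PHMcc	coding	missense	0.16	0.0026	0.0066	0	<0.05	likely benign (1, 5, 13)	likely_benign	1	5	13	likely_benign	FALSE	FALSE
c.718C>T	p.His240Tyr	rs761898981	exon 9	PHMcc	coding	missense	0.15	0.0039	0.0478	0	<0.05	VUS (0, 11, 7)	vus	0	11	7	vus	FALSE	FALSE
c.731T>C	p.Val244Ala	rs201009674	exon 10	PHMcc	coding	missense	0.16	0.0533	0.6632	0	n.s.	likely pathogenic (6, 12, 0)	likely_pathogenic	6	12	0	vus	FALSE	FALSE
c.1235C>T	p.Pro412Leu	rs761619241	exon 14	linker region	coding	missense	0.16	0.0016	0.0029	0	<0.05	likely pathogenic (6, 9, 4)	likely_pathogenic	6	9	4	vus	FALSE	FALSE
c.1354A>G	p.Ile452Val	rs145710876	exon 14	linker region	coding	missense	0.16	0.0151	0.0555	0	n.s.	likely benign (0, 0, 18)	likely_benign	0	0	18	likely_benign	FALSE	FALSE
c.1473A>C	p.Glu491Asp	rs61736661	exon 14	linker region	coding	missense	0.16	0.6662	1.241	8	n.s.	likely benign (0, 1, 16)	likely_benign	0	1	16	likely_benign	FALSE	FALSE
c.1616C>G	p.Ser539Trp	rs78408340	exon 16	PALcc	coding	missense	0.15	0.4169	0.7250	2	n.s.	likely pathogenic (10, 6, 2)	likely_pathogenic	10	6	2	likely_pathogenic	FALSE	TRUE
c.1654G>A	p.Gly552Arg	rs201249509	exon 16	PALcc	coding	missense	0.15	0.0053	0.0103	0	<0.05	likely pathogenic (10, 6, 2)	likely_pathogenic	10	6	2	likely_pathogenic	FALSE	FALSE
c.1688A>G	p.Asp563Gly	rs35658696	exon 16	PALcc	coding	missense	4.00	3.109	5.657	108	n.s.	likely pathogenic (4, 11, 1)	likely_pathogenic	4	11	1	vus	FALSE	TRUE
c.1921G>C	p.Gly641Arg	rs775364358	exon 18	PALcc	coding	missense	0.15	0.0033	0.0197	0	<0.05	likely benign (0, 3, 16)	likely_benign	0	3	16	likely_benign	FALSE	FALSE
c.2108G>A	p.Arg703Gln	rs761130902	exon 19	PALcc	coding	missense	0.15	0.0013	0.0193	0	<0.05	likely pathogenic (10, 9, 0)	likely_pathogenic	10	9	0	likely_pathogenic	FALSE	FALSE
c.2276T>C	p.Phe759Ser	rs375364507	exon 20	PALcc	coding	missense	0.15	0.0092	0.0206	0	n.s.	likely pathogenic (7, 11, 0)	likely_pathogenic	7	11	0	vus	FALSE	FALSE
c.2332-2A>T	p.His778fs	rs1006675725	intron 20	PALcc	coding	splice_acceptor	0.15	0.0007	0.0015	0	<0.05	pathogenic (disrupts canonical SA)	likely_pathogenic	NA	NA	NA	NA	TRUE	FALSE
c.*1455C>T	NA	rs146343559	3'UTR (exon 25)	NA	regulatory	utr	0.67	0.0362	0.1047	0	n.s.	creates new miRNA binding sites	NA	NA	NA	NA	NA	TRUE	FALSE
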