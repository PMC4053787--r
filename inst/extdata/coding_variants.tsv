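# Coding SNP and small-indel differences between C57BL/6J and C57BL/6N, as printed.
# Coordinates are 1-based positions on the NCBIM37 (mm9) reference.
# base_n "-" denotes a 1 bp deletion relative to the J allele.
# private_to: B6J / B6N = allele private to that sub-strain; B6N_shared = also seen in a wider strain panel (strain_label records the printed composite).
# as_printed_anomaly: TRUE where the printed row is internally inconsistent (Stxb4 repeats the gene symbol in the amino-acid column); aa_j is stored as missing.
chrom	pos	base_j	base_n	strain_label	private_to	gene	consequence	aa_j	aa_n	as_printed_anomaly
13	65023280	C	T	B6N	B6N	Spata31	nonsense	Arginine	stop	FALSE
1	59904011	G	A	B6N	B6N	Bmpr2	missense	Arginine	Glutamine	FALSE
3	95538799	T	C	B6J	B6J	Ecm1	missense	Isoleucine	Valine	FALSE
3	96658480	A	G	B6J	B6J	Pdzk1	missense	Asparagine	Aspartic acid	FALSE
4	21800831	C	G	B6J	B6J	Sfrs18	missense	Arginine	Glycine	FALSE
4	137777588	C	T	B6N	B6N	Hp1bp3	missense	Leucine	Phenylalanine	FALSE
4	140354038	A	G	B6N	B6N	Padi3	missense	Leucine	Proline	FALSE
4	148318468	T	C	B6J	B6J	Casz1	missense	Leucine	Proline	FALSE
5	90204376	C	T	B6N	B6N	Adamts3	missense	Valine	Isoleucine	FALSE
5	97187161	T	C	B6J	B6J	Fras1	missense	Leucine	Proline	FALSE
5	113191741	C	T	B6N	B6N	Myo18b	missense	Arginine	Histidine	FALSE
6	39350455	T	A	B6J	B6J	Mkrn1	missense	Asparagine	Tyrosine	FALSE
7	3222538	T	C	B6J	B6J	Nlrp12	missense	Lysine	Arginine	FALSE
7	63386662	G	A	B6J	B6J	Herc2	missense	Glycine	Aspartic acid	FALSE
7	86256240	A	C	B6J	B6J	Acan	missense	Histidine	Proline	FALSE
7	110121823	C	T	B6N	B6N	Olfr577	missense	Valine	Isoleucine	FALSE
7	127278693	G	A	B6N+Spretus	B6N_shared	Zp2	missense	Alanine	Valine	FALSE
7	129311164	C	T	B6N	B6N	Plk1	missense	Arginine	Tryptophan	FALSE
9	24935069	C	G	B6N	B6N	Herpud2	missense	Valine	Leucine	FALSE
10	66700922	T	C	B6J	B6J	Jmjd1c	missense	Leucine	Proline	FALSE
10	78632222	A	G	B6N	B6N	Vmn2r80	missense	Asparagine	Serine	FALSE
10	87554578	T	C	B6N	B6N	Pmch	missense	Isoleucine	Threonine	FALSE
11	46036117	G	A	B6N	B6N	Cyfip2	missense	Serine	Phenylalanine	FALSE
11	90341985	C	T	B6N	B6N	Stxb4	missense	NA	Threonine	TRUE
13	21560172	A	G	B6J	B6J	Nkapl	missense	Glycine	Arginine	FALSE
13	73465884	A	G	B6J	B6J	Ndufs6	missense	Valine	Alanine	FALSE
13	93833534	C	G	B6J	B6J	Cmya5	missense	Alanine	Proline	FALSE
14	70986011	G	T	B6N	B6N	Fam160b2	missense	Serine	Arginine	FALSE
15	11266138	G	T	B6N	B6N	Adamts12	missense	Cysteine	Phenylalanine	FALSE
15	77468437	A	C	B6J	B6J	Apol11b	missense	Isoleucine	Arginine	FALSE
16	35291630	G	A	B6N	B6N	Adcy5	missense	Valine	Methionine	FALSE
17	47537359	T	C	B6J	B6J	Guca1a	missense	Isoleucine	Valine	FALSE
X	131227581	C	A	B6N	B6N	Armcx4	missense	Alanine	Aspartic acid	FALSE
5	54280548	A	G	B6J	B6J	Tbc1d19	splice	NA	NA	FALSE
1	141133664	G	-	B6N	B6N	Crb1	frameshift	NA	NA	FALSE
9	65127938	G	-	B6J	B6J	Cilp	frameshift	NA	NA	FALSE
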