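patient	sex	concordance	gene	variant_class	notation	cdna	protein	size_label	inheritance
2	female	both	PACS1	snv	Chr11:g.65978677C>T	c.607C>T	p.(Arg203Trp)	NA	de_novo
12	male	both	SPEN	indel	Chr1:g.16257748_16257752del	c.5013_5017del	p.(Glu1671Aspfs*16)	NA	de_novo
30	male	both	TBR1	snv	Chr2:g.162273598T>A	c.677T>A	p.(Ile226Asn)	NA	de_novo
35	male	both	CDK13	indel	Chr7:g.39990724dup	c.484dup	p.(Ala162Glyfs*108)	NA	de_novo
35	male	both	TET3	snv	Chr2:g.74326613C>T	c.3478C>T	p.(Arg1160Cys)	NA	de_novo
39	female	both	ANKRD11	snv	Chr16:g.89346232C>A	c.6718G>T	p.(Glu2240*)	NA	de_novo
40	female	both	GATAD2B	indel	Chr1:g.153791300_153791301del	c.565_566del	p.(Gln190Alafs*34)	NA	de_novo
49	male	both	DOCK3	indel	Chr3:g.51127708_51127711dup	c.639_642dup	p.(Pro214Ilefs*7)	NA	homozygous
55	male	both	ANKRD11	indel	Chr16:g.89347820dup	c.5130dup	p.(Ser1711Ilefs*21)	NA	de_novo
57	male	both	SLC16A2	indel	ChrX:g.73641601del	c.351del	p.(Val118Cysfs*40)	NA	de_novo
63	female	both	MECP2	indel	ChrX:g.153296476del	c.842del	p.(Gly281Alafs*20)	NA	de_novo
66	female	both	SHANK3	snv	Chr22:g.51159604C>T	c.3391C>T	p.(Arg1131*)	NA	de_novo
67	male	both	CHD3	snv	Chr17:g.7803968G>A	c.3074G>A	p.(Arg1025Gln)	NA	de_novo
71	male	both	TRIP12	snv	Chr2:g.230632449G>T	c.6028C>A	p.(Pro2010Thr)	NA	de_novo
73	male	both	ATRX	snv	ChrX:g.76875938T>C	c.5197A>G	p.(Lys1733Glu)	NA	hemizygous
74	male	both	ACTB	snv	Chr7:g.5568193G>A	c.521C>T	p.(Ala174Val)	NA	de_novo
79	male	both	BMP4	snv	Chr14:g.54418925G>A	c.16C>T	p.(?)	NA	de_novo
80	male	both	ANKRD11	indel	Chr16:g.89351038_89351039del	c.1914_1915del	p.(His638Glnfs*24)	NA	de_novo
82	male	both	SHANK3	indel	Chr22:g.51159940dup	c.3727dup	p.(Ala1243Glyfs*69)	NA	de_novo
84	female	both	MYCN	snv	Chr2:g.16082228C>A	c.42C>A	p.(Cys14*)	NA	de_novo
86	male	both	WASF1	snv	Chr6:g.110422797G>A	c.1516C>T	p.(Arg506*)	NA	de_novo
88	male	both	CUL3	snv	Chr2:g.225371574C>G	c.1047+1G>C	p.(?)	NA	de_novo
96	female	both	DDX3X	indel	ChrX:g.41205496dup	c.1330dup	p.(Thr444Asnfs*21)	NA	de_novo
97	male	both	SLC2A1	snv	Chr1:g.43395707C>A	c.517-1G>T	p.(?)	NA	de_novo
98	male	both	ABCD1	snv	ChrX:g.153002655C>A	c.1438C>A	p.(Pro480Thr)	NA	hemizygous
102	female	both	DDX3X	snv	ChrX:g.41203054C>T	c.744C>T	p.(Gly248=)	NA	de_novo
107	male	both	KDM5C	snv	ChrX:g.53223539C>T	c.3820G>A	p.(Glu1274Lys)	NA	de_novo
109	male	both	PPM1D	indel	Chr17:g.58734161dup	c.1219dup	p.(Cys407Leufs*27)	NA	de_novo
110	female	both	FOXP2	snv	Chr7:g.114292307C>T	c.1219C>T	p.(Arg407*)	NA	de_novo
113	male	both	KCNQ2	snv	Chr20:g.62076675G>A	c.430C>T	p.(Arg144Trp)	NA	de_novo
116	female	both	FBXO11	snv	Chr2:g.48132751G>A	c.109C>T	p.(Gln37*)	NA	de_novo
120	male	both	ANKRD11	snv	Chr16:g.89349832T>A	c.3118A>T	p.(Lys1040*)	NA	de_novo
121	female	both	DEAF1	snv	Chr11:g.686982C>T	c.680G>A	p.(Cys227Tyr)	NA	de_novo
124	male	both	KAT6A	indel	Chr8:g.41791983del	c.3756del	p.(Ser1253Leufs*41)	NA	de_novo
132	female	both	DDX3X	snv	ChrX:g.41206602C>T	c.1807C>T	p.(Arg603*)	NA	de_novo
133	male	both	GRIA3	snv	ChrX:g.122561802G>A	c.1888G>A	p.(Gly630Arg)	NA	hemizygous
139	female	both	GNB1	snv	Chr1:g.1735941C>T	c.347G>A	p.(Gly116Asp)	NA	de_novo
140	male	both	NFIX	indel	Chr19:g.13184270del	c.681del	p.(Val229Serfs*4)	NA	de_novo
144	male	both	FOXG1	snv	Chr14:g.29237130C>A	c.645C>A	p.(Phe215Leu)	NA	de_novo
146	male	both	KCNQ2	snv	Chr20:g.62044909G>A	c.1657C>T	p.(Arg553Trp)	NA	de_novo
33	female	gs_only	CHD2	cnv	15q26.1(93494184-93499518)x1	NA	NA	5 kb	de_novo
47	female	gs_only	AHDC1	cnv	1p36.11(27833526-27869757)x1	NA	NA	36 kb	de_novo
8	female	both	CSNK2A1	cnv	20p13(486287-1783151)x1	NA	NA	1.3 Mb	de_novo
8	female	gs_only	PDYN	cnv	20p13(1963481-1995077)x3	NA	NA	32 kb	de_novo
25	male	both	FMR1	str	X:146993568_146993628CGG[94]	NA	NA	94 repeat units	anticipation
117	male	both	Multiple	cnv	16p11.2(29591089-30199431)3x	NA	NA	0.6 Mb	paternal
142	male	both	Multiple	cnv	16p13.2(8165983-9074579)1x	NA	NA	0.9 Mb	de_novo
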