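region_id	name	abbreviation	left_label	right_label	network
1	Precentral gyrus	PreCG	1	2	SMN
2	Superior frontal gyrus, dorsolateral	SFG	3	4	DMN
3	Middle frontal gyrus	MFG	5	6	other
4	Inferior frontal gyrus, opercular part	IFGoperc	7	8	other
5	Inferior frontal gyrus, triangular part	IFGtriang	9	10	other
6	Inferior frontal gyrus, orbital part	IFGorb	11	12	LIM
7	Rolandic operculum	ROL	13	14	SMN
8	Supplementary motor area	SMA	15	16	SMN
9	Olfactory cortex	OLF	17	18	LIM
10	Superior frontal gyrus, medial	SFGmedial	19	20	DMN
11	Ventromedial prefrontal cortex	PFCventmed	21	22	DMN
12	Gyrus rectus	REC	23	24	LIM
13	Medial orbitofrontal cortex	OFCmed	25	26	LIM
14	Anterior orbitofrontal cortex	OFCant	27	28	LIM
15	Posterior orbitofrontal cortex	OFCpost	29	30	LIM
16	Lateral orbitofrontal cortex	OFClat	31	32	LIM
17	Insula	INS	33	34	other
18	Anterior cingulate cortex	ACC	35	36	DMN
19	Median cingulate cortex	MCC	37	38	other
20	Posterior cingulate cortex	PCC	39	40	DMN
21	Hippocampus	HIP	41	42	LIM
22	Parahippocampal gyrus	PHG	43	44	LIM
23	Amygdala	AMYG	45	46	LIM
24	Calcarine fissure and surrounding cortex	CAL	47	48	other
25	Cuneus	CUN	49	50	other
26	Lingual gyrus	LING	51	52	other
27	Superior occipital gyrus	SOG	53	54	other
28	Middle occipital gyrus	MOG	55	56	other
29	Inferior occipital gyrus	IOG	57	58	other
30	Fusiform gyrus	FFG	59	60	other
31	Postcentral gyrus	PoCG	61	62	SMN
32	Superior parietal gyrus	SPG	63	64	SMN
33	Inferior parietal gyrus	IPG	65	66	other
34	Supramarginal gyrus	SMG	67	68	other
35	Angular gyrus	ANG	69	70	DMN
36	Precuneus	PCUN	71	72	DMN
37	Paracentral lobule	PCL	73	74	SMN
38	Caudate nucleus	CAU	75	76	other
39	Putamen	PUT	77	78	other
40	Pallidum	PAL	79	80	other
41	Thalamus	THA	81	82	other
42	Heschl gyrus	HES	83	84	SMN
43	Superior temporal gyrus	STG	85	86	other
44	Temporal pole, superior temporal gyrus	TPOsup	87	88	LIM
45	Middle temporal gyrus	MTG	89	90	DMN
46	Temporal pole, middle temporal gyrus	TPOmid	91	92	LIM
47	Inferior temporal gyrus	ITG	93	94	other
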