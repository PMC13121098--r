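region_id	name	hemisphere	is_cortical	volume	network
0	lh-bankssts	left	TRUE	4500	default
1	lh-caudalanteriorcingulate	left	TRUE	1900	ventralattention
2	lh-caudalmiddlefrontal	left	TRUE	6200	dorsalattention
3	lh-cuneus	left	TRUE	3100	visual
4	lh-entorhinal	left	TRUE	1700	limbic
5	lh-fusiform	left	TRUE	9800	visual
6	lh-inferiorparietal	left	TRUE	13200	default
7	lh-inferiortemporal	left	TRUE	10900	limbic
8	lh-isthmuscingulate	left	TRUE	2500	default
9	lh-lateraloccipital	left	TRUE	11700	visual
10	lh-lateralorbitofrontal	left	TRUE	7500	limbic
11	lh-lingual	left	TRUE	6400	visual
12	lh-medialorbitofrontal	left	TRUE	5400	limbic
13	lh-middletemporal	left	TRUE	11000	default
14	lh-parahippocampal	left	TRUE	2100	limbic
15	lh-paracentral	left	TRUE	3600	somatomotor
16	lh-parsopercularis	left	TRUE	4400	frontoparietal
17	lh-parsorbitalis	left	TRUE	2200	frontoparietal
18	lh-parstriangularis	left	TRUE	3700	frontoparietal
19	lh-pericalcarine	left	TRUE	2200	visual
20	lh-postcentral	left	TRUE	9900	somatomotor
21	lh-posteriorcingulate	left	TRUE	3100	default
22	lh-precentral	left	TRUE	13100	somatomotor
23	lh-precuneus	left	TRUE	9700	default
24	lh-rostralanteriorcingulate	left	TRUE	2400	default
25	lh-rostralmiddlefrontal	left	TRUE	15600	frontoparietal
26	lh-superiorfrontal	left	TRUE	22500	default
27	lh-superiorparietal	left	TRUE	12200	dorsalattention
28	lh-superiortemporal	left	TRUE	11500	somatomotor
29	lh-supramarginal	left	TRUE	10100	ventralattention
30	lh-frontalpole	left	TRUE	1200	default
31	lh-temporalpole	left	TRUE	2400	limbic
32	lh-transversetemporal	left	TRUE	1300	somatomotor
33	lh-insula	left	TRUE	6600	ventralattention
34	rh-bankssts	right	TRUE	4590	default
35	rh-caudalanteriorcingulate	right	TRUE	1938	ventralattention
36	rh-caudalmiddlefrontal	right	TRUE	6324	dorsalattention
37	rh-cuneus	right	TRUE	3162	visual
38	rh-entorhinal	right	TRUE	1734	limbic
39	rh-fusiform	right	TRUE	9996	visual
40	rh-inferiorparietal	right	TRUE	13464	default
41	rh-inferiortemporal	right	TRUE	11118	limbic
42	rh-isthmuscingulate	right	TRUE	2550	default
43	rh-lateraloccipital	right	TRUE	11934	visual
44	rh-lateralorbitofrontal	right	TRUE	7650	limbic
45	rh-lingual	right	TRUE	6528	visual
46	rh-medialorbitofrontal	right	TRUE	5508	limbic
47	rh-middletemporal	right	TRUE	11220	default
48	rh-parahippocampal	right	TRUE	2142	limbic
49	rh-paracentral	right	TRUE	3672	somatomotor
50	rh-parsopercularis	right	TRUE	4488	frontoparietal
51	rh-parsorbitalis	right	TRUE	2244	frontoparietal
52	rh-parstriangularis	right	TRUE	3774	frontoparietal
53	rh-pericalcarine	right	TRUE	2244	visual
54	rh-postcentral	right	TRUE	10098	somatomotor
55	rh-posteriorcingulate	right	TRUE	3162	default
56	rh-precentral	right	TRUE	13362	somatomotor
57	rh-precuneus	right	TRUE	9894	default
58	rh-rostralanteriorcingulate	right	TRUE	2448	default
59	rh-rostralmiddlefrontal	right	TRUE	15912	frontoparietal
60	rh-superiorfrontal	right	TRUE	22950	default
61	rh-superiorparietal	right	TRUE	12444	dorsalattention
62	rh-superiortemporal	right	TRUE	11730	somatomotor
63	rh-supramarginal	right	TRUE	10302	ventralattention
64	rh-frontalpole	right	TRUE	1224	default
65	rh-temporalpole	right	TRUE	2448	limbic
66	rh-transversetemporal	right	TRUE	1326	somatomotor
67	rh-insula	right	TRUE	6732	ventralattention
68	Left-Thalamus-Proper	left	FALSE	7600	subcortical
69	Left-Caudate	left	FALSE	3600	subcortical
70	Left-Putamen	left	FALSE	5200	subcortical
71	Left-Pallidum	left	FALSE	1800	subcortical
72	Left-Hippocampus	left	FALSE	4200	subcortical
73	Left-Amygdala	left	FALSE	1700	subcortical
74	Left-Accumbens-area	left	FALSE	600	subcortical
75	Left-VentralDC	left	FALSE	4000	subcortical
76	Left-Cerebellum-Cortex	left	FALSE	54000	cerebellar
77	Right-Thalamus-Proper	right	FALSE	7828	subcortical
78	Right-Caudate	right	FALSE	3708	subcortical
79	Right-Putamen	right	FALSE	5356	subcortical
80	Right-Pallidum	right	FALSE	1854	subcortical
81	Right-Hippocampus	right	FALSE	4326	subcortical
82	Right-Amygdala	right	FALSE	1751	subcortical
83	Right-Accumbens-area	right	FALSE	618	subcortical
84	Right-VentralDC	right	FALSE	4120	subcortical
85	Right-Cerebellum-Cortex	right	FALSE	55620	cerebellar
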