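# PTPN11 exon-3 amplicon site lookup (127 sites: 108 coding c.138..c.245, 19 intronic).
# ref bases with ref_source=table are as printed in the transcribed variant table;
# ref_source=synthetic bases (including all intronic bases and the codon context
# below) are fixed synthetic filler -- NOT the RefSeq NM_002834.5 sequence.
# context_c136=A context_c137=A context_c246=G
local_index	site_label	ref	region	codon	codon_pos	ref_source
1	c.138-9	T	intron			synthetic
2	c.138-8	T	intron			synthetic
3	c.138-7	C	intron			synthetic
4	c.138-6	T	intron			synthetic
5	c.138-5	T	intron			synthetic
6	c.138-4	T	intron			synthetic
7	c.138-3	C	intron			synthetic
8	c.138-2	A	intron			synthetic
9	c.138-1	G	intron			synthetic
10	c.138	C	coding	46	3	synthetic
11	c.139	T	coding	47	1	synthetic
12	c.140	T	coding	47	2	synthetic
13	c.141	T	coding	47	3	synthetic
14	c.142	T	coding	48	1	synthetic
15	c.143	A	coding	48	2	synthetic
16	c.144	C	coding	48	3	synthetic
17	c.145	G	coding	49	1	synthetic
18	c.146	C	coding	49	2	synthetic
19	c.147	A	coding	49	3	synthetic
20	c.148	T	coding	50	1	synthetic
21	c.149	T	coding	50	2	synthetic
22	c.150	A	coding	50	3	synthetic
23	c.151	C	coding	51	1	synthetic
24	c.152	C	coding	51	2	synthetic
25	c.153	C	coding	51	3	synthetic
26	c.154	A	coding	52	1	table
27	c.155	C	coding	52	2	table
28	c.156	C	coding	52	3	table
29	c.157	G	coding	53	1	synthetic
30	c.158	T	coding	53	2	synthetic
31	c.159	A	coding	53	3	synthetic
32	c.160	C	coding	54	1	synthetic
33	c.161	G	coding	54	2	synthetic
34	c.162	A	coding	54	3	synthetic
35	c.163	A	coding	55	1	table
36	c.164	A	coding	55	2	table
37	c.165	G	coding	55	3	table
38	c.166	A	coding	56	1	table
39	c.167	T	coding	56	2	table
40	c.168	C	coding	56	3	table
41	c.169	C	coding	57	1	synthetic
42	c.170	A	coding	57	2	synthetic
43	c.171	G	coding	57	3	synthetic
44	c.172	A	coding	58	1	table
45	c.173	A	coding	58	2	table
46	c.174	C	coding	58	3	table
47	c.175	A	coding	59	1	table
48	c.176	C	coding	59	2	table
49	c.177	A	coding	59	3	table
50	c.178	G	coding	60	1	table
51	c.179	G	coding	60	2	table
52	c.180	A	coding	60	3	table
53	c.181	G	coding	61	1	table
54	c.182	A	coding	61	2	table
55	c.183	T	coding	61	3	table
56	c.184	T	coding	62	1	table
57	c.185	A	coding	62	2	table
58	c.186	C	coding	62	3	table
59	c.187	T	coding	63	1	table
60	c.188	A	coding	63	2	table
61	c.189	C	coding	63	3	table
62	c.190	G	coding	64	1	synthetic
63	c.191	T	coding	64	2	synthetic
64	c.192	C	coding	64	3	synthetic
65	c.193	T	coding	65	1	synthetic
66	c.194	A	coding	65	2	synthetic
67	c.195	T	coding	65	3	synthetic
68	c.196	C	coding	66	1	synthetic
69	c.197	C	coding	66	2	synthetic
70	c.198	A	coding	66	3	synthetic
71	c.199	T	coding	67	1	synthetic
72	c.200	G	coding	67	2	synthetic
73	c.201	T	coding	67	3	synthetic
74	c.202	A	coding	68	1	synthetic
75	c.203	G	coding	68	2	synthetic
76	c.204	G	coding	68	3	synthetic
77	c.205	G	coding	69	1	table
78	c.206	A	coding	69	2	table
79	c.207	A	coding	69	3	table
80	c.208	C	coding	70	1	synthetic
81	c.209	C	coding	70	2	synthetic
82	c.210	A	coding	70	3	synthetic
83	c.211	T	coding	71	1	table
84	c.212	T	coding	71	2	table
85	c.213	T	coding	71	3	table
86	c.214	G	coding	72	1	table
87	c.215	C	coding	72	2	table
88	c.216	C	coding	72	3	table
89	c.217	A	coding	73	1	table
90	c.218	C	coding	73	2	table
91	c.219	T	coding	73	3	table
92	c.220	T	coding	74	1	table
93	c.221	T	coding	74	2	table
94	c.222	G	coding	74	3	table
95	c.223	T	coding	75	1	synthetic
96	c.224	T	coding	75	2	synthetic
97	c.225	G	coding	75	3	synthetic
98	c.226	G	coding	76	1	table
99	c.227	A	coding	76	2	table
100	c.228	G	coding	76	3	table
101	c.229	T	coding	77	1	table
102	c.230	T	coding	77	2	table
103	c.231	G	coding	77	3	table
104	c.232	A	coding	78	1	synthetic
105	c.233	A	coding	78	2	synthetic
106	c.234	G	coding	78	3	synthetic
107	c.235	C	coding	79	1	table
108	c.236	A	coding	79	2	table
109	c.237	G	coding	79	3	table
110	c.238	A	coding	80	1	synthetic
111	c.239	T	coding	80	2	synthetic
112	c.240	T	coding	80	3	synthetic
113	c.241	C	coding	81	1	synthetic
114	c.242	A	coding	81	2	synthetic
115	c.243	C	coding	81	3	synthetic
116	c.244	A	coding	82	1	table
117	c.245	T	coding	82	2	table
118	c.245+1	G	intron			synthetic
119	c.245+2	T	intron			synthetic
120	c.245+3	A	intron			synthetic
121	c.245+4	A	intron			synthetic
122	c.245+5	G	intron			synthetic
123	c.245+6	T	intron			synthetic
124	c.245+7	A	intron			synthetic
125	c.245+8	C	intron			synthetic
126	c.245+9	T	intron			synthetic
127	c.245+10	C	intron			synthetic
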