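cds_label	local_index	ref	alt	region	consequence	category	ns_cases	cosmic_cases	clusters
c.155C>G	27	C	G	coding	missense	SO_cancer	0	2	""
c.155C>T	27	C	T	coding	missense	rare_NS1	2	0	""
c.166A>G	38	A	G	coding	missense	rare_NS1	2	0	68
c.172A>C	44	A	C	coding	missense	rare_NS1	7	0	""
c.172A>G	44	A	G	coding	missense	recurrent_NS1	20	0	65
c.172A>T	44	A	T	coding	missense	SO_cancer	0	8	""
c.173A>G	45	A	G	coding	missense	rare_NS1	1	0	""
c.174C>A	46	C	A	coding	missense	rare_NS1	3	0	""
c.174C>G	46	C	G	coding	missense	rare_NS1	6	0	""
c.175A>G	47	A	G	coding	missense	rare_NS1	1	0	""
c.178G>A	50	G	A	coding	missense	rare_NS1	2	0	68
c.178G>C	50	G	C	coding	missense	SO_cancer	0	7	""
c.178G>T	50	G	T	coding	missense	rare_NS1	1	0	""
c.179G>C	51	G	C	coding	missense	recurrent_NS1	25	0	68
c.179G>T	51	G	T	coding	missense	SO_cancer	0	40	""
c.181G>A	53	G	A	coding	missense	recurrent_NS1	50	0	""
c.181G>C	53	G	C	coding	missense	rare_NS1	3	0	65;68
c.181G>T	53	G	T	coding	missense	SO_cancer	0	52	""
c.182A>C	54	A	C	coding	missense	rare_NS1	1	0	""
c.182A>G	54	A	G	coding	missense	recurrent_NS1	49	0	65;68
c.182A>T	54	A	T	coding	missense	SO_cancer	0	49	68
c.184T>A	56	T	A	coding	missense	rare_NS1	1	0	""
c.184T>G	56	T	G	coding	missense	recurrent_NS1	42	0	65
c.188A>G	60	A	G	coding	missense	recurrent_NS1	110	0	65;68
c.205G>A	77	G	A	coding	missense	SO_cancer	0	27	""
c.205G>C	77	G	C	coding	missense	rare_NS1	9	0	""
c.206A>T	78	A	T	coding	missense	rare_NS1	2	0	""
c.211T>A	83	T	A	coding	missense	rare_NS1	1	0	""
c.211T>C	83	T	C	coding	missense	rare_NS1	5	0	65;68
c.213T>A	85	T	A	coding	missense	SO_cancer	0	9	""
c.213T>G	85	T	G	coding	missense	SO_cancer	0	1	""
c.214G>A	86	G	A	coding	missense	SO_cancer	0	45	65;68
c.214G>C	86	G	C	coding	missense	rare_NS1	1	0	65
c.214G>T	86	G	T	coding	missense	recurrent_NS1	26	0	""
c.215C>A	87	C	A	coding	missense	SO_cancer	0	6	68
c.215C>G	87	C	G	coding	missense	recurrent_NS1	26	0	68
c.215C>T	87	C	T	coding	missense	SO_cancer	0	64	""
c.218C>T	90	C	T	coding	missense	recurrent_NS1	33	20	68
c.220T>A	92	T	A	coding	missense	SO_cancer	0	1	""
c.226G>A	98	G	A	coding	missense	SO_cancer	0	111	68
c.226G>C	98	G	C	coding	missense	SO_cancer	0	17	""
c.227A>C	99	A	C	coding	missense	SO_cancer	0	17	""
c.227A>G	99	A	G	coding	missense	SO_cancer	0	48	68
c.227A>T	99	A	T	coding	missense	SO_cancer	0	12	68
c.228G>C	100	G	C	coding	missense	recurrent_NS1	16	0	""
c.228G>T	100	G	T	coding	missense	rare_NS1	5	0	68
c.229T>G	101	T	G	coding	missense	SO_cancer	0	1	""
c.236A>C	108	A	C	coding	missense	rare_NS1	2	0	""
c.236A>G	108	A	G	coding	missense	recurrent_NS1	75	0	68
c.245T>C	117	T	C	coding	missense	SO_cancer	0	1	""
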