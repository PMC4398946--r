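animal	hemisphere	field	alpha_deg	freq_dir_deg	freq_r2	freq_p	rate_dir_deg	rate_r2	rate_p	n_vertices
M1	L	A1	137	162	0.796	<1E-16	25	0.636	<1E-16	84
M1	R	A1	73	155	0.546	<1E-16	82	0.696	<1E-16	101
M2	L	A1	120	175	0.927	<1E-16	56	0.884	<1E-16	154
M2	R	A1	133	160	0.803	<1E-16	66	0.750	<1E-16	103
M3	L	A1	121	164	0.824	<1E-16	43	0.699	<1E-16	156
M3	R	A1	128	175	0.722	<1E-16	47	0.675	<1E-16	87
M1	L	R	81	38	0.106	1.40E-02	120	0.782	<1E-16	88
M1	R	R	140	23	0.391	2.89E-11	117	0.600	<1E-16	107
M2	L	R	51	29	0.697	<1E-16	80	0.420	2.00E-09	102
M2	R	R	103	44	0.441	2.50E-10	147	0.660	<1E-16	93
M3	L	R	180	81	0.476	1.40E-10	100	0.255	4.20E-06	87
M3	R	R	148	9	0.611	4.20E-15	157	0.691	<1E-16	73
M1	L	CL	161	13	0.577	2.80E-04	148	0.587	1.70E-06	33
M1	R	CL	113	109	0.516	3.30E-07	138	0.264	1.90E-03	44
M2	L	CL	163	42	0.563	3.30E-07	155	0.582	2.00E-12	40
M2	R	CL	102	14	0.552	5.70E-10	116	0.559	<1E-16	58
M3	L	CL	168	27	0.795	3.30E-16	165	0.751	2.60E-14	48
M3	R	CL	158	2	0.706	4.20E-11	156	0.768	4.20E-13	42
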