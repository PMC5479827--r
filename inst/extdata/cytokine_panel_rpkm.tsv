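symbol	description	mc_rpkm	lc_rpkm	log2_printed	family
IL22	interleukin 22	2.11	11.27	-2.42	cytokine
IL19	interleukin 19	84.30	306.20	-1.86	cytokine
IL1B	interleukin 1 beta	6.95	14.43	-1.05	cytokine
IL26	interleukin 26	7.69	3.34	1.20	cytokine
IL33	interleukin 33	24.37	11.53	1.08	cytokine
LOC102170310	C-C motif chemokine 15	12.80	29.18	-1.19	cytokine
LOC102181154	C-C motif chemokine 3	1.21	3.35	-1.47	cytokine
CXCL8	C-X-C motif chemokine ligand 8	41.09	153.22	-1.90	cytokine
CX3CL1	C-X3-C motif chemokine ligand 1	0.80	2.35	-1.56	cytokine
CXCL11	C-X-C motif chemokine ligand 11	2.06	5.08	-1.30	cytokine
LOC102174969	C-C motif chemokine 8	11.57	5.16	1.17	cytokine
CXCL14	C-X-C motif chemokine ligand 14	194.03	86.38	1.17	cytokine
TGFB1	transforming growth factor beta 1	1.39	3.54	-1.35	cytokine
RDH13	retinol dehydrogenase 13	2.86	6.31	-1.14	enzyme
ALDH1A3	aldehyde dehydrogenase 1 family member A3	11.92	25.31	-1.09	enzyme
ALDH16A1	aldehyde dehydrogenase 16 family member A1	2.33	4.73	-1.02	enzyme
ALDH4A1	aldehyde dehydrogenase 4 family member A1	2.90	8.32	-1.52	enzyme
ALDH1A1	aldehyde dehydrogenase 1 family member A1	1420.73	558.50	1.35	enzyme
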