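symbol	description	mc_rpkm	lc_rpkm	log2_printed	family
LOC102180073	sialic acid-binding Ig-like lectin 14	0.03	1.33	-5.47	siglec
FCN1	ficolin 1	0.93	4.98	-2.42	galectin
CLEC7A	C-type lectin domain family 7, member A	0.65	1.84	-1.50	CLR
LOC102181776	sialic acid-binding Ig-like lectin 14	0.78	1.89	-1.28	siglec
LOC102184901	C-type lectin domain family 2 member D11-like	65.59	147.84	-1.17	CLR
CLEC4E	C-type lectin domain family 4, member E	1.27	2.82	-1.15	CLR
LGALS9	lectin, galactoside-binding, soluble, 9	5.40	11.44	-1.08	galectin
CLEC16A	C-type lectin domain family 16, member A	2.11	4.35	-1.04	CLR
LGALS3BP	lectin, galactoside-binding, soluble, 3 binding protein	3.24	6.65	-1.04	galectin
LMAN2	lectin, mannose-binding 2	30.76	62.86	-1.03	CLR
LGALS15	lectin, galactoside-binding, soluble, 15	1.50	0.64	1.23	galectin
LOC106503212	C-type lectin domain family 10 member A-like	3.99	1.96	1.03	CLR
LOC102189655	C-type lectin domain family 2 member D11-like	2.48	1.24	1.00	CLR
LOC102180339	galectin-7	393.68	486.38	-0.31	galectin
LOC102180072	galectin-7	280.25	327.80	-0.23	galectin
CLEC3B	C-type lectin domain family 3, member B	263.21	205.23	0.36	CLR
LGALS3	lectin, galactoside-binding, soluble, 3	99.80	108.23	-0.12	galectin
LGALSL	lectin, galactoside-binding-like	114.98	99.52	0.21	galectin
LGALS1	lectin, galactoside-binding, soluble, 1	148.30	86.79	0.77	galectin
OS9	OS9, endoplasmic reticulum lectin	42.99	49.58	-0.21	CLR
ERLEC1	endoplasmic reticulum lectin 1	25.02	21.84	0.20	CLR
LOC106504001	C-type lectin domain family 1 member A-like	20.86	20.86	0.00	CLR
LMAN1	lectin, mannose-binding, 1	12.35	14.85	0.00	CLR
LGALS8	lectin, galactoside-binding, soluble, 8	14.36	14.59	0.27	galectin
LGALS4	lectin, galactoside-binding, soluble, 4	10.33	7.80	0.02	galectin
LOC102180574	C-type lectin domain family 6 member A	7.15	6.63	-0.41	CLR
COLEC12	collectin sub-family member 12	6.82	5.96	-0.11	CLR
LOC102180291	C-type lectin domain family 4 member A	4.92	3.52	-0.19	CLR
CLEC5A	C-type lectin domain family 5, member A	1.63	2.01	-0.48	CLR
CLEC12A	C-type lectin domain family 12, member A	2.17	1.82	0.30	CLR
CLEC2A	C-type lectin domain family 2, member A	2.89	1.69	-0.25	CLR
CLEC1A	C-type lectin domain family 1, member A	2.47	1.51	-0.77	CLR
LMAN2L	lectin, mannose-binding 2-like	0.89	1.50	-0.71	CLR
CLEC14A	C-type lectin domain family 14, member A	0.88	1.36	0.75	CLR
LOC102189932	C-type lectin domain family 2 member H-like	1.66	1.02	0.63	CLR
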