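residue	steric	polarizability	isoelectric	hydrophobicity	helix_prob	vdw_volume	sheet_prob
A	1.28	0.05	6.11	0.31	0.42	1.00	0.23
R	2.34	0.29	10.74	-1.01	0.36	6.13	0.25
N	1.60	0.13	6.52	-0.60	0.21	2.95	0.22
D	1.60	0.11	2.95	-0.77	0.25	2.78	0.20
C	1.77	0.13	6.35	1.54	0.17	2.43	0.41
Q	1.56	0.18	5.65	-0.22	0.36	3.95	0.25
E	1.56	0.15	3.09	-0.64	0.42	3.78	0.21
G	0.00	0.00	6.07	0.00	0.13	0.00	0.15
H	2.99	0.23	7.69	0.13	0.27	4.66	0.30
I	4.19	0.19	6.04	1.80	0.30	4.00	0.45
L	2.59	0.19	6.04	1.70	0.39	4.00	0.31
K	1.89	0.22	9.99	-0.99	0.32	4.77	0.27
M	2.35	0.22	5.71	1.23	0.38	4.43	0.32
F	2.94	0.29	5.67	1.79	0.30	5.89	0.38
P	2.67	0.00	6.80	0.72	0.13	2.72	0.34
S	1.31	0.06	5.70	-0.04	0.20	1.60	0.28
T	3.03	0.11	5.60	0.26	0.21	2.60	0.36
W	3.21	0.41	5.94	2.25	0.32	8.08	0.42
Y	2.94	0.30	5.66	0.96	0.25	6.47	0.41
V	3.67	0.14	6.02	1.22	0.27	3.00	0.49
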