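residue	hydrophobicity	polarity	polarizability	solvent_accessibility	net_charge_index	molecular_weight	pK_N	pK_C	melting_point	optical_rotation	entropy_of_formation	heat_capacity	absolute_entropy	hydrophilicity
A	1.8	8.1	0.046	129	0.007187	89.09	9.69	2.34	297	1.8	154.33	29.22	30.88	-0.5
C	2.5	5.5	0.128	167	-0.03661	121.16	10.28	1.96	178	-16.5	219.79	50.7	53.83	-1.0
D	-3.5	13.0	0.105	193	-0.02382	133.10	9.60	1.88	270	5.05	194.91	37.09	40.66	3.0
E	-3.5	12.3	0.151	223	0.006802	147.13	9.67	2.19	249	12.0	223.16	41.84	44.98	3.0
F	2.8	5.2	0.290	240	0.037552	165.19	9.13	1.83	283	-34.5	204.74	48.52	51.06	-2.5
G	-0.4	9.0	0.000	104	0.179052	75.07	9.60	2.34	290	0.0	127.90	23.71	24.74	0.0
H	-3.2	10.4	0.230	224	-0.01069	155.16	9.17	1.82	287	-38.5	242.54	59.64	65.99	-0.5
I	4.5	5.2	0.186	197	0.021631	131.17	9.68	2.36	284	12.4	233.21	45.00	49.71	-1.8
K	-3.9	11.3	0.219	236	0.017708	146.19	8.95	2.18	224	14.6	300.46	57.10	63.21	3.0
L	3.8	4.9	0.186	201	0.051672	131.17	9.60	2.36	337	-11.0	232.30	48.03	50.62	-1.8
M	1.9	5.7	0.221	224	0.002683	149.21	9.21	2.28	283	-10.0	202.65	69.32	55.32	-1.3
N	-3.5	11.6	0.134	195	0.005392	132.12	8.80	2.02	236	-5.60	207.90	38.30	41.70	0.2
P	-1.6	8.0	0.131	159	0.239531	115.13	10.60	1.99	222	-86.2	179.93	36.13	39.21	0.0
Q	-3.5	10.5	0.180	225	0.049211	146.15	9.13	2.17	185	6.3	235.51	44.02	46.45	0.2
R	-4.5	10.5	0.291	274	0.043587	174.20	9.04	2.17	238	12.5	341.01	26.37	68.43	3.0
S	-0.8	9.2	0.062	155	0.004627	105.09	9.15	2.21	228	-7.5	174.06	32.40	35.65	0.3
T	-0.7	8.6	0.108	172	0.003352	119.12	9.10	2.09	253	-28.0	205.80	35.20	36.50	-0.4
V	4.2	5.9	0.140	174	0.057004	117.15	9.62	2.32	293	5.63	207.60	40.35	42.75	-1.5
W	-0.9	5.4	0.409	285	0.037977	204.23	9.39	2.83	282	-33.7	237.01	56.92	60.00	-3.4
Y	-1.3	6.2	0.298	263	0.023599	181.19	9.11	2.20	344	-10.0	229.15	51.73	51.15	-2.3
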