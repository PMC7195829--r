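property	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
hydropathy_kd	1.8	-4.5	-3.5	-3.5	2.5	-3.5	-3.5	-0.4	-3.2	4.5	3.8	-3.9	1.9	2.8	-1.6	-0.8	-0.7	-0.9	-1.3	4.2
residue_mass	71.08	156.19	114.1	115.09	103.14	128.13	129.12	57.05	137.14	113.16	113.16	128.17	131.19	147.18	97.12	87.08	101.1	186.21	163.18	99.13
sim_index_01	-13.41	-21.98	-4.93	-11.73	5.68	-15.48	-0.44	-12.6	12.67	10.4	-8.37	-4.94	-11.02	9.83	0.53	-6.5	3.05	-17.8	-10.83	-4.15
sim_index_02	-0.3	1.22	8.33	-12	3.81	21.12	-15.85	4.21	-7.88	-7.23	10.18	-5.07	0.37	-5.42	-2.73	-22.35	4.17	12.23	6.62	0.8
sim_index_03	19.3	21.64	10.1	8.93	-11.44	-12.87	-2.49	11.64	-5.8	-16.07	-11.65	7.41	-12.57	-2.53	-7.02	-4.61	-12.61	-2.91	3.51	4.57
sim_index_04	-5.29	18.41	3.47	1.56	-8.31	0.91	-1.27	0.22	-2.66	11.43	9.55	-2.75	-17.31	-18.83	18.34	9.81	-4.98	5.3	-12.06	-3.67
sim_index_05	3.47	-4.51	0.25	1.64	-4.86	-6.03	-2.49	-0.7	19.25	-0.5	-11.37	-3.64	8.51	-20.52	-0.94	-1.32	-11.24	-10.93	8.85	-2.74
sim_index_06	1.19	-0.16	0.19	0.33	-1.1	-0.79	-0.18	1.11	0.81	1.72	0.57	-1.08	-0.15	0.75	-0.98	0.1	-0.34	0.16	-0.82	-0.19
sim_index_07	-6.08	0.49	3.87	5.57	-13.61	-17.16	-5.87	10.98	-0.79	-2.59	-0.37	-13.63	-7.44	6.09	-3.37	1.52	-11.46	6.58	-7.76	2.83
sim_index_08	0.76	-0.35	0.99	0.66	0.77	-1.31	-0.44	1.53	-0.59	-0.56	-1.09	-0.47	-0.46	-0.15	0.39	-0.65	0.06	-0.35	-0.27	-0.53
sim_index_09	92.96	-1.84	-58.01	-158.25	-42.1	-25.8	-107.2	13.03	45.46	-4.37	-80.57	-81.04	23.32	-8.19	40.22	2.46	-185.59	-82.35	-117.9	-55.44
sim_index_10	-71.83	-121.5	-97.4	-58.34	117.46	173.95	-87.58	-36.54	-212.94	-21.2	-23.06	-84.14	37.64	-39.44	123.82	-138.28	-33.97	122.61	-92.96	-71.44
sim_index_11	-0.65	-0.24	-1.69	-1	-1.19	1.25	0.62	1.96	-1.41	0.96	0.08	-0.51	0.3	-0.54	0.4	-1.08	1.19	0.89	-0.9	0.52
sim_index_12	-1.25	31.54	-13.25	-3.63	-22	-26.54	-8.89	-16.16	-16.01	15.85	-4.19	-1.04	8.71	2.8	-12.02	10.2	-13.86	-10.22	-7.47	10.84
sim_index_13	-108.32	48.36	18.67	26.64	-52.05	-89.81	156.41	-34.7	-35.32	-85.12	-18.66	-133.64	-116.64	11.05	-123.56	97.68	-33.21	-65.67	23.98	-109.84
sim_index_14	4.25	-9.24	-6.14	-3.42	-4.72	18.84	12.88	9.19	-4.8	5.37	5.25	-5.32	-6.29	-1.15	1.53	7.67	14.47	-6.08	-3.08	-12.72
sim_index_15	-23.87	-1.35	9.58	8.62	-12.91	-18.78	-1.55	-1.39	-21.78	4.79	-15.83	5.05	-6.36	7.68	3.16	-7.32	-27	14.39	-1.4	21.96
sim_index_16	0.57	0.64	0.85	1.65	0.32	-0.96	-1.34	-1.66	0.39	1.29	-0.23	-0.04	-1.71	-0.27	1.29	-0.11	-0.05	0.41	0.22	0.05
sim_index_17	5.22	-2.93	7.58	2.34	11.04	14.27	-5.4	-2.07	3.54	3.6	13.47	4.96	14.67	-0.78	1.64	11.96	-7.3	2.6	-12.43	-12.19
sim_index_18	-0.61	106.22	40.37	-7.21	-76.75	-32.73	-8.32	21.47	-43.63	-214.12	216.05	-30.27	-129.24	65.5	-63.28	-62.43	-109.55	95.63	122.76	-48.38
sim_index_19	-36.66	183.37	88.51	-30.19	-104.99	53.35	-23.94	-103.06	122.8	-200.12	-129.62	-4.41	-120.79	198.5	-47.57	-22.24	-77.19	31.47	69.76	122.92
sim_index_20	26.03	224.11	11.4	-84.45	-58.35	9.16	138.31	133.44	-215.13	134.44	-27.9	43.17	99.13	34.02	-26.29	272.24	129.6	-75.28	-35.65	-50.98
sim_index_21	1.02	-1.48	7.25	-2.38	2.85	4.21	5.82	12.08	-12.99	7.28	0.48	2.79	-1.48	0.08	-14.33	-14.06	-0.06	-8.84	3.07	-5.47
sim_index_22	10.53	-6.09	2.86	3.85	-13.06	-6.47	2.19	-13.56	7.74	-0.44	17.19	19.54	-3.27	18.08	-8.65	3.36	-7.85	11.26	-4.76	7.7
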