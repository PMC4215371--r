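doc_id	group	tobacco	product	smoke	health	state	consum	warn	member	market	packag	cigarett	commiss	impact	direct	european_union
Consultation	eu	5.17	4.79	1.05	1.50	3.07	1.12	1.57	3.00	1.57	1.42	1.27	0.15	0.15	1.35	0.52
Commission	eu	3.78	4.05	0.57	1.29	2.39	0.75	1.24	2.37	0.98	0.82	0.75	1.24	0.04	1.51	0.15
Final	eu	4.04	4.19	0.67	1.21	2.25	0.58	1.18	2.25	0.95	0.90	0.75	1.01	0.03	1.40	0.10
ESC	health	0.27	0.33	0.30	0.19	0.07	0.11	0.08	0.07	0.02	0.05	0.04	0.05	0.08	0.05	0.11
EPHA1	health	3.89	2.88	0.62	2.02	1.63	0.86	2.41	1.09	1.63	1.32	1.09	0.39	0.23	0.70	0.54
EPHA2	health	4.89	4.49	0.80	1.68	1.04	0.40	1.20	1.12	0.96	1.28	0.64	0.56	0.32	0.72	1.28
ECL/SFP	health	4.36	3.17	1.09	2.38	0.99	0.30	2.87	0.79	0.69	0.99	1.68	0.10	0.20	0.79	0.20
EFA	health	2.57	1.97	2.72	2.27	0.15	0.30	1.82	0.15	0.00	1.66	0.61	0.15	0.30	0.30	0.30
PML	tobacco	1.11	2.02	0.96	0.98	1.04	0.34	0.41	0.85	1.40	0.39	1.53	2.54	1.32	0.47	1.50
PMI1	tobacco	2.65	1.72	2.08	0.72	1.04	0.48	0.40	0.68	0.72	0.72	1.72	0.40	0.36	0.44	0.80
PMI2	tobacco	1.65	0.69	1.25	1.19	0.65	0.37	0.69	0.39	0.96	0.73	0.87	0.47	2.00	0.19	1.03
ECMA	tobacco	2.33	2.74	0.82	1.22	1.17	1.40	1.69	1.22	0.82	1.40	0.12	0.47	0.06	0.06	0.29
CECCM	tobacco	1.80	0.36	0.00	0.00	0.90	0.36	0.00	0.54	0.90	0.00	0.00	1.26	3.77	1.26	0.00
IT	tobacco	1.69	2.51	0.56	1.01	1.13	1.01	0.98	1.13	0.90	0.30	0.75	2.14	0.26	0.83	1.24
JTI	tobacco	0.42	0.44	3.50	1.12	0.28	2.39	0.87	0.09	0.31	0.55	0.86	0.19	0.45	0.13	0.06
ESTA	tobacco	6.67	4.17	0.92	0.75	0.79	0.79	0.48	0.61	1.01	0.61	0.75	0.22	0.83	1.05	0.83
EFFAT	other	4.53	1.46	1.05	0.57	0.00	0.16	0.16	0.00	0.57	0.32	0.81	0.32	0.97	0.32	1.78
ECTA	other	2.57	2.76	0.00	0.37	0.18	1.10	0.18	0.00	0.18	2.21	0.18	0.18	0.18	0.37	0.92
RWG	other	2.85	2.39	0.97	0.66	0.56	0.71	0.10	0.41	1.37	0.76	0.66	0.41	0.25	0.15	1.32
EMMA	other	2.72	2.72	0.00	0.00	0.63	0.63	0.21	0.42	0.00	0.00	0.21	0.21	0.42	1.26	0.63
ACC	other	2.12	6.35	0.00	0.18	1.06	0.35	0.00	0.00	1.59	3.70	0.00	0.00	0.00	0.88	0.71
TrMark	other	0.19	1.32	0.00	1.13	0.00	1.32	0.94	1.13	0.38	1.70	0.00	0.38	0.19	0.19	0.38
GM	other	2.74	5.16	0.32	2.26	0.16	1.45	2.10	0.16	1.13	3.71	0.00	0.00	0.00	0.32	0.00
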