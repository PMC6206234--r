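group	label	or	ci_low	ci_high	p	power
rs110419	AG vs. AA	0.62	0.46	0.82	0.001	0.361
rs110419	GG vs. AA	0.65	0.44	0.97	0.034	0.458
rs110419	AG/GG vs. AA	0.63	0.48	0.82	0.0006	0.317
rs110419	age <= 18	0.63	0.42	0.94	0.022	0.377
rs110419	age > 18	0.63	0.44	0.90	0.011	0.358
rs110419	females	0.64	0.43	0.95	0.025	0.400
rs110419	males	0.62	0.43	0.89	0.009	0.329
rs110419	retroperitoneal	0.46	0.32	0.68	0.0001	0.031
rs4758051	AG vs. GG	0.63	0.47	0.84	0.002	0.415
rs4758051	AA vs. GG	0.68	0.47	0.99	0.046	0.547
rs4758051	AG/AA vs. GG	0.64	0.49	0.84	0.001	0.377
rs4758051	age > 18	0.59	0.41	0.84	0.004	0.236
rs4758051	males	0.60	0.41	0.86	0.006	0.271
rs4758051	retroperitoneal	0.49	0.34	0.72	0.0002	0.054
rs10840002	AG vs. AA	0.68	0.51	0.92	0.012	0.666
rs10840002	GG/AG vs. AA	0.74	0.56	0.97	0.031	0.764
rs10840002	retroperitoneal	0.61	0.42	0.90	0.013	0.330
rs2168101	GT vs. GG	0.51	0.38	0.69	0.0001	0.045
rs2168101	TT vs. GG	0.51	0.28	0.95	0.034	0.192
rs2168101	GT/TT vs. GG	0.51	0.39	0.68	0.0001	0.035
rs2168101	age <= 18	0.66	0.44	0.98	0.040	0.470
rs2168101	age > 18	0.40	0.27	0.60	0.0001	0.008
rs2168101	females	0.62	0.42	0.93	0.020	0.363
rs2168101	males	0.43	0.29	0.64	0.0001	0.016
rs2168101	retroperitoneal	0.48	0.32	0.72	0.0004	0.062
rs2168101	mediastinum	0.51	0.32	0.79	0.003	0.120
combined	4-5 vs. 0-3	0.52	0.40	0.69	0.0001	0.042
combined	age <= 18	0.61	0.41	0.91	0.014	0.320
combined	age > 18	0.45	0.31	0.66	0.0001	0.027
combined	females	0.60	0.40	0.90	0.013	0.300
combined	males	0.46	0.32	0.68	0.0001	0.033
combined	retroperitoneal	0.41	0.27	0.62	0.0001	0.014
combined	mediastinum	0.56	0.36	0.86	0.009	0.211
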