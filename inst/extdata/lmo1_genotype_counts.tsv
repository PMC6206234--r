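rsid	genotype	n_case	n_control
rs110419	0	150	279
rs110419	1	118	355
rs110419	2	45	128
rs4758051	0	138	256
rs4758051	1	123	364
rs4758051	2	52	142
rs10840002	0	120	240
rs10840002	1	128	375
rs10840002	2	65	147
rs204938	0	200	476
rs204938	1	97	258
rs204938	2	16	28
rs2168101	0	214	401
rs2168101	1	85	310
rs2168101	2	14	51
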