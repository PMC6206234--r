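haplotype	n_case	n_control
AGAAG	271	606
AGAAT	0	2
AGAGG	33	67
AGGAG	16	10
AGGGG	7	8
AGGGT	0	1
AAAAG	1	5
AAGAG	54	156
AAGAT	0	1
AAGGG	36	57
GGAAG	39	106
GGAAT	9	24
GGAGG	12	37
GGAGT	0	6
GGGAG	6	1
GGGAT	3	5
GGGGG	2	1
GGGGT	1	2
GAAAG	2	1
GAAAT	1	1
GAGAG	21	29
GAGAT	74	263
GAGGG	13	28
GAGGT	25	107
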