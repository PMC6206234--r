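score_group	n_case	n_control
0-3	213	401
4-5	100	361
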