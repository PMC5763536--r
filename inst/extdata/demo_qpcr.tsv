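sample	group	target_ct	control_ct
S01	NSCLC	23.7	21.54
S02	NSCLC	24.01	21.92
S03	NSCLC	23.24	21.66
S04	NSCLC	23.32	22
S05	NSCLC	24.59	21.93
S06	NSCLC	23.53	22.27
S07	CTRL	26.66	21.82
S08	CTRL	26.31	21.8
S09	CTRL	25.98	21.8
S10	CTRL	25.5	22
S11	CTRL	25.59	21.87
S12	CTRL	25.83	22.11
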