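lncrna_a	lncrna_b	shared_mirnas	p	q	weight
L04	L05	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L04	L06	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L04	L07	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L04	L08	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L05	L06	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L05	L07	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L05	L08	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L06	L07	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L06	L08	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L07	L08	3	0.0285714285714285	0.0285714285714285	1.54406804435028
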