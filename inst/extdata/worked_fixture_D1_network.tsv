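lncrna_a	lncrna_b	shared_mirnas	p	q	weight
L01	L02	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L01	L03	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L01	L04	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L01	L05	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L02	L03	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L02	L04	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L02	L05	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L03	L04	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L03	L05	3	0.0285714285714285	0.0285714285714285	1.54406804435028
L04	L05	3	0.0285714285714285	0.0285714285714285	1.54406804435028
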