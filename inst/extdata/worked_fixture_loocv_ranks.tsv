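disease	held_out	rank	n_candidates	percentile
D1	L01	4	6	0.666666666666667
D1	L02	4	6	0.666666666666667
D1	L04	1	6	0.166666666666667
D2	L04	1	6	0.166666666666667
D2	L06	4	6	0.666666666666667
D2	L07	4	6	0.666666666666667
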