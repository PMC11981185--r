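threshold	score
0.1	0.7687
0.25	0.7593
0.5	0.7680
0.75	0.7613
0.9	0.7593
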