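level	description	sample_size
1	Very alert	278
2	Relatively alert	1305
3	Some signs of sleepiness	3463
4	Sleepy	2497
5	Extremely sleepy	396
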