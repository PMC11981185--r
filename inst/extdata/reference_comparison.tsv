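method	accuracy	deviation	accuracy_sleepy	deviation_sleepy
drnrf	94.2	0.004	94.3	0.067
ann	58.3	0.079	56.6	0.485
gbm	64.8	0.108	64.4	0.398
knn	74.8	-0.040	73.0	0.375
rf	76.7	0.025	74.1	0.304
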