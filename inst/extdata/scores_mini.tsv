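domain_a	domain_b	score_local	score_global
1lq7A00	2oo2A00	0.730000	0.700000
1lq7A00	2qe9A01	0.730000	0.480000
2oo2A00	2qe9A01	0.410000	0.350000
2qe9A01	1lq7A00	0.730000	0.480000
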