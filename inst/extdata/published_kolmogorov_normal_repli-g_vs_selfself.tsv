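#metric	kolmogorov
#mode	between
#group_a	Normal Amp-R/UnAmp
#group_b	Normal UnAmp/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0.398	0.402	0.405	0.402
Replicate 2	0.409	0.413	0.416	0.413
Replicate 3	0.385	0.389	0.392	0.388
Replicate 4	0.415	0.419	0.423	0.420
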