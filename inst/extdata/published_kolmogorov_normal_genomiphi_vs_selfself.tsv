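#metric	kolmogorov
#mode	between
#group_a	Normal Amp-G/UnAmp
#group_b	Normal UnAmp/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0.370	0.354	0.386	0.342
Replicate 2	0.381	0.366	0.398	0.354
Replicate 3	0.357	0.340	0.373	0.328
Replicate 4	0.388	0.373	0.405	0.361
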