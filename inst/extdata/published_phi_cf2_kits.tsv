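#metric	phi
#mode	between
#group_a	CF2 Amp-R/UnAmp
#group_b	CF2 Amp-G/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0.762	0.771	0.833	0.835
Replicate 2	0.776	0.773	0.831	0.818
Replicate 3	0.789	0.839	0.782	0.795
Replicate 4	0.736	0.741	0.825	0.828
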