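#metric	phi
#mode	between
#group_a	CF1 Amp-R/UnAmp
#group_b	CF1 Amp-G/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0.736	0.804	0.906	0.681
Replicate 2	0.842	0.782	0.711	0.807
Replicate 3	0.828	0.804	0.815	0.738
Replicate 4	0.733	0.692	0.622	0.796
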