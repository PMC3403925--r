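#metric	kolmogorov
#mode	within
#group_a	CF1 Amp-R/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0	0.108	0.046	0.065
Replicate 2	0.108	0	0.062	0.062
Replicate 3	0.046	0.062	0	0.120
Replicate 4	0.065	0.062	0.120	0
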