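#metric	kolmogorov
#mode	within
#group_a	Normal UnAmp/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0	0.019	0.026	0.024
Replicate 2	0.019	0	0.044	0.018
Replicate 3	0.026	0.044	0	0.049
Replicate 4	0.024	0.018	0.049	0
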