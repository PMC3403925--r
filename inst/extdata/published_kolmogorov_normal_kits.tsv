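#metric	kolmogorov
#mode	between
#group_a	Normal Amp-R/UnAmp
#group_b	Normal Amp-G/UnAmp
	Replicate 1	Replicate 2	Replicate 3	Replicate 4
Replicate 1	0.031	0.055	0.026	0.078
Replicate 2	0.038	0.063	0.035	0.085
Replicate 3	0.041	0.065	0.037	0.088
Replicate 4	0.032	0.051	0.019	0.072
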