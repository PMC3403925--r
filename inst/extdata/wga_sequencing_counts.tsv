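sample	kit	examined	mutations
Normal	repli-g	7900	0
CF1	repli-g	7924	0
CF2	repli-g	7909	0
Normal	genomiphi	7888	0
CF1	genomiphi	7905	0
CF2	genomiphi	7906	0
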