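kit	excluded	aligned
genomiphi	53	23744
repli-g	11	23744
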