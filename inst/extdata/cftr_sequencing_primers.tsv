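primer_name	location	sequence	tm	amplicon_size
Seq1_F	112776-112797	GGACATCTCCAAGTTTGCAGAG	66	760
Seq1_R	113535-113512	GAAACATTTGACATCAGAGTCAC	64
Seq2_F	113459-113479	GTCAAGGAGAGAGCTTTGTGG	64	729
Seq2_R	114187-114165	TGGACAACACATTACACATTCTG	64
Seq3_F	114050-114071	GGCTTCTAGACATCCAACATAG	64	756
Seq3_R	114805-114784	GATAGCAGTGCTGCCACAACTG	68
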