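# HR-HPV status counts per diagnostic group, from a published
# cervicovaginal microbiome cohort (n = 86).
group	status	n
Normal	Negative	14
Normal	Positive	12
LSIL	Negative	3
LSIL	Positive	22
HSIL	Negative	0
HSIL	Positive	25
CCU	Negative	0
CCU	Positive	10
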