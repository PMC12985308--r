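# Number of genera retained after per-group prevalence filtering in a
# published cervicovaginal co-occurrence network analysis.
group	n_nodes
Normal	7
LSIL	15
HSIL	10
CCU	11
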