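# Significant co-occurrence edges per diagnostic group (|rho| >= 0.6 for
# Normal/LSIL/HSIL, |rho| >= 0.7 for CCU; q < 0.05) from a published
# cervicovaginal microbiome cohort.
group	genus1	genus2	rho
Normal	Dialister	Peptoniphilus	0.68615385
LSIL	Escherichia	Shigella	0.77569170
LSIL	Dialister	Anaerococcus	0.70750988
LSIL	Dialister	Prevotella	0.68873518
HSIL	Finegoldia	Peptoniphilus	0.74000000
HSIL	Dialister	Peptoniphilus	0.68695652
CCU	Dialister	Hoylesella	0.98787879
CCU	Anaerococcus	Peptoniphilus	0.92727273
CCU	Anaerococcus	Pseudomonas	-0.85454545
CCU	Peptoniphilus	Campylobacter	0.85454545
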