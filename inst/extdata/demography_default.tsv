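# Default three-population demography (times in generations ago, sizes are
# diploid Ne). African population at near-constant size; the non-African
# populations share an out-of-Africa bottleneck with later recovery.
# Backwards in time CHBJPT merges into CEU (their shared ancestor), which
# merges into YRI. Values are declared defaults, editable per run.
record	population	time	size	ancestral
epoch	YRI	0	12000	NA
epoch	YRI	3500	10000	NA
epoch	CEU	0	10000	NA
epoch	CEU	1000	1500	NA
epoch	CHBJPT	0	9000	NA
epoch	CHBJPT	800	1200	NA
split	CHBJPT	1500	NA	CEU
split	CEU	3500	NA	YRI
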