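# published per-receptor inferred network sizes, androgen-sensitive vs androgen-independent cell line (top ten by gain)
tf	network_size_before	network_size_after
PGR	1	53
RXRA	3	52
RARG	2	44
RORA	0	30
NR4A3	1	29
NR5A2	0	27
ESR2	0	23
VDR	18	41
NR2C1	0	22
ESRRG	22	42
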