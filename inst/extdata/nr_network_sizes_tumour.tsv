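# published per-receptor inferred network sizes, paired clinical samples pre/post androgen deprivation (top ten by gain)
tf	network_size_before	network_size_after
PGR	28	114
ESRRA	2	77
PPARD	2	65
THRB	32	95
ESR2	29	67
NR2F6	4	37
NR4A2	5	35
ESRRG	21	41
RXRG	7	24
NR1I3	26	39
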