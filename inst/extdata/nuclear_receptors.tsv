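symbol
AR
ESR1
ESR2
ESRRA
ESRRB
ESRRG
NR3C1
NR3C2
PGR
RARA
RARB
RARG
RXRA
RXRB
RXRG
RORA
RORB
RORC
THRA
THRB
VDR
PPARA
PPARD
PPARG
NR1D1
NR1D2
NR1H2
NR1H3
NR1H4
NR1I2
NR1I3
HNF4A
HNF4G
NR2C1
NR2C2
NR2E1
NR2E3
NR2F1
NR2F2
NR2F6
NR4A1
NR4A2
NR4A3
NR5A1
NR5A2
NR6A1
NR0B1
NR0B2
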