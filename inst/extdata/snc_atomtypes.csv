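# Atom-type map used when emitting GROMACS include files for SNC
atom,type
N,N
H,H
CA,CT
HA,H1
CB,CT
HB1,H1
HB2,H1
SG,S
ND,NO
OE,ON
C,C
O,O
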