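# Published partial atomic charges (e) for the S-nitroso-L-cysteine residue
# (atoms not involved in the amide bond)
atom,charge
CA,-0.0218
HA,0.0758
CB,0.4533
HB1,-0.0674
HB2,-0.0674
SG,-0.1959
ND,0.0855
OE,-0.1468
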