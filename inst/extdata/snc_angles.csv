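# Published equilibrium angles (deg) and harmonic bending force constants
# (kJ mol-1 rad-2) for S-nitroso-L-cysteine
a1,a2,a3,theta_eq,k_theta
HB1,CB,SG,107.5,293.0
CA,CB,SG,113.8,487.5
CB,SG,ND,99.5,1137.0
SG,ND,OE,117.2,1283.1
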