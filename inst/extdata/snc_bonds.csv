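# Published equilibrium bond distances (nm) and harmonic stretching force
# constants (kJ mol-1 nm-2) for S-nitroso-L-cysteine
a1,a2,req,kb
CB,SG,0.1803,129555.1
SG,ND,0.1918,79743.2
ND,OE,0.1170,695768.8
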