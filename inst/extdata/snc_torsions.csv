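# Published torsion series for S-nitroso-L-cysteine:
# V = sum k_phi * (1 + cos(n*phi - phi_s)); k_phi kJ mol-1, phi_s deg
a1,a2,a3,a4,phi_s,k_phi,n
CA,CB,SG,ND,180,0.2399,1
CA,CB,SG,ND,0,1.4742,2
HB1,CB,SG,ND,180,1.4613,3
CB,SG,ND,OE,0,1.0769,1
CB,SG,ND,OE,180,27.2930,2
CB,SG,ND,OE,180,2.7214,3
CB,SG,ND,OE,180,0.5033,4
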