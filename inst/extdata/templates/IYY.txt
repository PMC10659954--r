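CODE IYY
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM SG S N CA CB 1.808 114.0 CHI1
ATOM SD S CA CB SG 2.040 103.0 CHI2
ATOM CB2 C CB SG SD 1.810 103.0 90
ATOM CA2 C SG SD CB2 1.530 114.0 180
ATOM N2 N SD CB2 CA2 1.460 110.0 -65
ATOM C2 C SD CB2 CA2 1.530 110.0 170
ATOM O2 O CB2 CA2 C2 1.231 121.0 0
CHI1 N CA CB SG 180
CHI2 CA CB SG SD 180
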