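CODE CGL
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM SG S N CA CB 1.808 114.0 CHI1
ATOM SD S CA CB SG 2.050 103.0 CHI2
ATOM CB2 C CB SG SD 1.810 103.0 90
ATOM CA2 C SG SD CB2 1.530 114.0 180
ATOM N2 N SD CB2 CA2 1.460 110.0 -65
ATOM C2 C SD CB2 CA2 1.530 110.0 170
ATOM O2 O CB2 CA2 C2 1.231 121.0 0
ATOM N3 N CB2 CA2 C2 1.329 116.2 180
ATOM CA3 C CA2 C2 N3 1.451 121.7 180
ATOM C3 C C2 N3 CA3 1.516 110.0 180
ATOM O31 O N3 CA3 C3 1.249 118.4 0
ATOM O32 O N3 CA3 C3 1.249 118.4 180
ATOM CD1 C CB2 CA2 N2 1.329 121.0 120
ATOM OE1 O CA2 N2 CD1 1.231 123.0 0
ATOM CG1 C CA2 N2 CD1 1.516 115.0 180
ATOM CB1 C N2 CD1 CG1 1.520 112.0 180
ATOM CA1 C CD1 CG1 CB1 1.530 112.0 180
ATOM N1 N CG1 CB1 CA1 1.460 110.0 -65
ATOM C1 C CG1 CB1 CA1 1.530 110.0 65
ATOM O11 O CB1 CA1 C1 1.249 118.4 0
ATOM O12 O CB1 CA1 C1 1.249 118.4 180
CHI1 N CA CB SG 180
CHI2 CA CB SG SD 180
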