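CODE CSD
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM SG S N CA CB 1.808 114.0 CHI1
ATOM OD1 O CA CB SG 1.470 106.0 CHI2
ATOM OD2 O CA CB SG 1.470 106.0 CHI2+110
CHI1 N CA CB SG 180
CHI2 CA CB SG OD1 60
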