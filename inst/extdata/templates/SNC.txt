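CODE SNC
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM SG S N CA CB 1.803 113.8 CHI1
ATOM ND N CA CB SG 1.918 99.5 CHI2
ATOM OE O CB SG ND 1.170 117.2 180
CHI1 N CA CB SG 180
CHI2 CA CB SG ND 180
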