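CODE GLN
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.520 114.1 CHI1
ATOM CD C CA CB CG 1.516 112.6 CHI2
ATOM OE1 O CB CG CD 1.231 120.8 0
ATOM NE2 N CB CG CD 1.328 116.4 180
CHI1 N CA CB CG 180
CHI2 CA CB CG CD 180
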