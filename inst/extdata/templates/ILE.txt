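CODE ILE
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG1 C N CA CB 1.530 110.4 CHI1
ATOM CG2 C N CA CB 1.521 110.5 CHI1-122
ATOM CD1 C CA CB CG1 1.513 113.8 CHI2
CHI1 N CA CB CG1 180
CHI2 CA CB CG1 CD1 170
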