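CODE HIS
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.504 113.8 CHI1
ATOM ND1 N CA CB CG 1.378 122.7 CHI2
ATOM CD2 C CA CB CG 1.356 131.0 CHI2+180
ATOM CE1 C CB CG ND1 1.321 109.2 180
ATOM NE2 N CB CG CD2 1.374 107.1 180
CHI1 N CA CB CG 180
CHI2 CA CB CG ND1 90
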