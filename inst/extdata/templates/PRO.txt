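CODE PRO
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.495 104.5 CHI1
ATOM CD C CA CB CG 1.507 106.1 CHI2
CHI1 N CA CB CG 30
CHI2 CA CB CG CD -35
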