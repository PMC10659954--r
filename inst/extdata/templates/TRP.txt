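CODE TRP
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.498 113.6 CHI1
ATOM CD1 C CA CB CG 1.365 126.9 CHI2
ATOM CD2 C CA CB CG 1.433 126.7 CHI2+180
ATOM NE1 N CB CG CD1 1.374 110.2 180
ATOM CE2 C CB CG CD2 1.409 107.2 180
ATOM CE3 C CB CG CD2 1.398 133.9 0
ATOM CZ2 C CG CD2 CE2 1.394 122.4 180
ATOM CZ3 C CG CD2 CE3 1.382 118.6 180
ATOM CH2 C CD2 CE2 CZ2 1.368 117.5 0
CHI1 N CA CB CG 180
CHI2 CA CB CG CD1 90
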