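CODE PHE
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.502 113.8 CHI1
ATOM CD1 C CA CB CG 1.384 120.8 CHI2
ATOM CD2 C CA CB CG 1.384 120.8 CHI2+180
ATOM CE1 C CB CG CD1 1.382 120.8 180
ATOM CE2 C CB CG CD2 1.382 120.8 180
ATOM CZ C CG CD1 CE1 1.382 120.0 0
CHI1 N CA CB CG 180
CHI2 CA CB CG CD1 90
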