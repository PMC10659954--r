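CODE ARG
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
ATOM CG C N CA CB 1.520 114.1 CHI1
ATOM CD C CA CB CG 1.520 111.3 CHI2
ATOM NE N CB CG CD 1.461 112.0 180
ATOM CZ C CG CD NE 1.329 124.2 180
ATOM NH1 N CD NE CZ 1.326 120.0 0
ATOM NH2 N CD NE CZ 1.326 120.0 180
CHI1 N CA CB CG 180
CHI2 CA CB CG CD 180
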