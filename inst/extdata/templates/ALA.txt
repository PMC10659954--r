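CODE ALA
ATOM N N -
ATOM CA C -
ATOM C C -
ATOM O O N CA C 1.231 120.5 PSI-180
ATOM CB C C N CA 1.526 110.5 -122.5
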