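Package: ptmforge
Title: In-Silico Post-Translational Modification of Protein Structures and
    Force-Field Parameterization for Non-Standard Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to introduce post-translational modifications (PTMs) into
    protein structures in silico and to carry the modified residues through a
    molecular-modelling workflow. Provides internal-coordinate model building
    (NERF), quaternion superposition, rotamer clash scanning, a registry of
    cysteine and other PTM reactions, derivation of harmonic bond and angle
    force constants from quantum-chemistry Hessians (modified Seminario method
    with singular value decomposition), multi-conformational RESP charge
    fitting, cosine-series torsion fitting, GROMACS topology emission, SLTCAP
    ion counting with protein-volume exclusion, deterministic generation of
    QM/MD/docking workflow artifacts, and post-simulation analysis (persistent
    close contacts, RMSF, Bennett acceptance ratio free energies). Ships the
    complete published parameter set for S-nitroso-L-cysteine and seeded
    synthetic-fixture generators so the entire pipeline is testable without
    external engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d
Config/testthat/edition: 3
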