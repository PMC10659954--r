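---
title: "Modelling cysteine PTMs and parameterizing non-standard residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cysteine PTMs and parameterizing non-standard residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmforge)
```

`ptmforge` covers the desk-side computations of a PTM modelling workflow:
editing modified residues into structures, deriving force-field parameters
for them from quantum-chemistry data, planning the engine-side workflow as
text, and analyzing its statistical output. This vignette records the
models, conventions and numerical decisions, in enough detail that every
result is reproducible from the description alone.

## Structure model and geometry

Coordinates are stored in Angstrom throughout the structure layer —
conversion to nm happens once, at the force-field/engine-facing boundary.
Residue numbering is taken verbatim from the input and never rewritten;
insertion codes are carried but not interpreted, and site strings
(`"A:CYS155"`, `"A:155"`) address (chain, number) only. Alternate locations
are resolved at parse time to the highest-occupancy copy, ties broken by
file order.

Internal-to-Cartesian building uses NERF: an atom is placed from three
reference positions and a (bond, angle, torsion) triple. The local frame
takes the b→c direction as first axis and the normal of the (a, b, c) plane
as third axis, so placements are bit-reproducible. Torsions follow the
IUPAC convention (cis = 0, right-handed positive) and are reported in
(−180, 180], so the planar trans case reads +180. `nerf_place()` and
`measure_internal()` are mutual inverses to well below 1e−6 over random
inputs; a collinear reference triple (triple-product below 1e−8) is
rejected rather than silently producing an arbitrary frame.

Superposition uses the quaternion (Horn) method: the rotation is derived
from the principal eigenvector of the 4x4 cross-covariance matrix and is
therefore always a proper rotation, even for degenerate point sets where
SVD-based fitting can reflect.

Bond perception declares two atoms bonded when their distance is below 120%
of the sum of their covalent radii (bundled single-bond radius table). A
*clash* is a heavy-atom pair closer than the sum of the van der Waals radii
minus 0.6 Å — the criterion has exactly one tunable constant (`overlap`),
exposed in `count_clashes()`. Hydrogens are ignored by the clash test: the
residue templates are heavy-atom models, and a hydrogen-aware criterion
would bind the result to a protonation model this package deliberately
delegates elsewhere.

## Residue templates and PTM editing

Templates (one versioned text file per residue under
`inst/extdata/templates/`) hold the ordered heavy-atom roster, per-atom
NERF recipes, chi1/chi2 definitions with default values, and implicitly the
default backbone conformation: the extended beta strand (φ, ψ = −135, 135),
used whenever the caller does not specify torsions. The alpha-helix
reference conformation is (−60, −45). Amide geometry for `prepend`/`append`
is the standard trans amide (ω = 180°, C–N 1.329 Å). For `append`, `psi` is
the ψ of the formerly terminal residue and `phi` the φ of the new one;
`prepend` is symmetric. The SNC side-chain geometry is seeded from the
bundled equilibrium values (C–S 1.803 Å, S–N 1.918 Å, N–O 1.170 Å; C–S–N
99.5°, S–N–O 117.2°).

`mutate()` keeps the backbone atoms (N, CA, C, O) of the edited residue
exactly fixed and rebuilds the side chain from the template. `modify()`
looks the (residue, reaction) pair up in the bundled registry and grows the
new moiety by NERF from an attachment stem of three existing atoms. The
printed registry is exposed verbatim by `list_modifications()`;
hydroxyl acetylation of SER/THR/TYR is additionally *performable* (it is
the package's own worked example) but deliberately not listed, and
N-terminal acetylation is reachable only through `prepend`, never through
`modify`, to avoid confusion with side-chain acetylation. Reaction names
fold case and accept the published aliases (nitrosation, carbamoylation,
and both "demethylation"/"dimethylation" spellings for arginine — the
registry stores the printed strings and aliases both rather than guessing
which was intended). Because the templates are heavy-atom models, leaving
groups (always hydrogens for the bundled reactions) are implicit.

The clash-avoidance scan is deterministic: chi1 is the outer loop and chi2
the inner one, both starting at the template default and stepping +30°
(12 x 12 = 144 combinations); the first clash-free combination wins,
otherwise the least-clash conformation is kept and a warning recorded. The
scan order is a package decision — any fixed order would do, but it must be
fixed for reproducibility.

## Modified Seminario constants

Bond constants are read off the interatomic 3x3 sub-block −∂²E/∂r_i∂r_j of
the Hessian. The sub-block of a general molecule is not symmetric, so
instead of its (possibly complex) eigendecomposition we use the singular
value decomposition and project the singular triples onto the unit bond
vector: `kb = Σ σ_m |v_m·û|²`. The absolute-value projection can only
overshoot the bilinear form û'(−H)û, so derived bond constants are, if
anything, slightly stiff; on an analytic water-like Hessian the overshoot
is below 1%.

For the bending constant of angle i–j–k we project the 1–3 sub-block
−∂²E/∂r_i∂r_k onto the two in-plane perpendicular unit vectors u_Pi and
u_Pk and scale by the arm lengths:
`kθ = R_ij R_kj Σ σ_m |u_m·u_Pi| |v_m·u_Pk|`. This choice is deliberate.
The more common two-sided formula
`1/kθ = 1/(k_Pi R_ij²) + 1/(k_Pk R_kj²)` built from the i–j and k–j
sub-blocks systematically underestimates a pure bend — on an analytic
triatomic with a single harmonic bend of 500 kJ mol⁻¹ rad⁻² it returns
about 336 (the exact factor for equal arms is (1 − cos θ)/2 under
eigenprojection) — whereas the 1–3 sub-block of a bonded force field
carries only the 1–3 couplings and reproduces the generating constant
exactly. Angle recovery on analytic harmonic Hessians is therefore an
honest 1% test of the implementation, not of a convention.

Angles whose central atom is shared by sibling angles receive a geometric
correction: each arm's contribution is divided by one plus the summed
squared overlaps of the perpendicular vectors of siblings sharing that
bond. Angles with no sibling at their center (for SNC, C–S–N and S–N–O)
are returned uncorrected and flagged as such — their constants remain the
ones most likely to be overestimated. When two conformer Hessians (alpha
and beta) are supplied, derived constants and equilibrium values are
averaged with equal weights; averaging derived constants rather than raw
matrices keeps the operation well defined when the two geometries differ.

Degenerate inputs fail loudly: a near-zero sub-block norm (atoms that do
not interact in the Hessian) raises a degenerate-Hessian error, and
collinear angle atoms are rejected.

## RESP charges

The fit minimizes the summed squared ESP error over all conformers (equal
weights — the published procedure is multi-conformational without stating
weights) plus the hyperbolic restraint `a(√(q² + b²) − b)` on non-hydrogen
atoms, solved as an iterated linear KKT system (the restraint enters as a
diagonal term `a/√(q² + b²)` refreshed each iteration, converged to 1e−12).
Hard constraints — the total charge, fixed-total groups such as the ACE/NME
capping groups, and frozen amide charges when matching an existing force
field — are enforced exactly via Lagrange multipliers. The standard
two-stage recipe is available: stage 1 fits all atoms with a = 0.0005,
stage 2 refits a nominated subset (methyl/methylene) with equivalence
classes at a = 0.001, everything else frozen; b = 0.1 throughout. These
constants are the conventional choice for the recipe and are exposed as
arguments. ESP units are e/Å with Coulomb constant 1; the fixture
generator uses the same convention, which is what makes restraint-free
recovery of generating point charges exact to rounding.

Failure modes are explicit: inconsistent constraint systems raise an
"infeasible" error, and a rank-deficient design (too few grid points, too
many equivalences) is reported as such rather than silently regularized.

## Torsion series

`fit_torsion_series()` fits `V(φ) = Σ k_n (1 + cos(nφ − φ_s))` with phases
restricted to {0, 180}. Under that restriction `cos(nφ − 180) = −cos(nφ)`,
so the model is linear in signed amplitudes; negative amplitudes are
absorbed as 180° phases, and a free intercept absorbs the arbitrary energy
zero of min-shifted profiles. All supplied conformer profiles are fitted
simultaneously. The published orthogonal-relaxation restraints (dihedrals
at ≥ 14,000 kJ mol⁻¹ rad⁻², positions at 418 kJ mol⁻¹ nm⁻²) belong to the
engine-side scan configuration and are therefore constants of
`gen_torsion_fit_config()`, not of the in-package fit — no MD engine runs
here, so there is nothing for those restraints to act on.

## Ion counts and volumes

SLTCAP ion counts use the closed form `N± = N0(√(1 + t²) ∓ t)` with
`N0 = c0·NA·V_water` and `t = Q/(2N0)`; the identity `N+·N− = N0²` is
asserted to 1e−9 as an internal cross-check, and both counts are rounded
half-up, which preserves exact neutrality because the continuous difference
is exactly −Q. The water volume is the box volume (rhombic dodecahedron
supported, V = √2/2·d³) minus the protein volume, summed from a bundled
per-residue table. That table is a constructed stand-in (standard mean
volumes of buried residues plus group increments for the PTM residues and
caps), labelled synthetic in its filename; users with access to a specific
tessellation-derived table can swap it without code changes.

## TI schedule and BAR

The default alchemical plan decouples electrostatics first, then van der
Waals together with masses and bonded terms, each stage over the 13-value
ladder λ = 0.00, 0.05, 0.10, 0.20, …, 0.90, 0.95, 1.00. Thirteen plus
thirteen values with the fully coupled boundary state shared gives the
25-leg flattened plan of 1 ns legs; the shared-boundary reading is encoded
explicitly because the two printed counts (13 steps, 25 simulations) are
only consistent under it.

BAR works in kT (the self-consistency equation is unit-free there;
`kt_to_kj_per_mol()` converts). The estimate solves
`Σ_F f(M + W_F − ΔG) = Σ_R f(−M + W_R + ΔG)` (f the Fermi function,
M = log nF/nR) by bracketed root finding to 1e−10 — the left-minus-right
difference is monotone in ΔG, so the bracket always closes. The uncertainty
is the standard asymptotic variance; when the two work distributions barely
overlap the variance estimate diverges and the result carries an explicit
warning flag instead of a silent number.

## Contacts and RMSF

A residue is a persistent close contact of a site when any of its atoms is
within 0.35 nm of any site-residue atom in at least 70% of frames;
sequence neighbours i±1 of the same chain are excluded as peptide-bonded.
The persistence denominator is all supplied frames — equilibration trimming
is the caller's decision, kept outside the operation. RMSF superposes each
frame onto the mean structure, recomputes the mean and refits once, then
reports per-atom root-mean-square deviations from the mean.

## What the synthetic fixtures do and do not show

The fixture generators produce exactly the inputs the methods consume, with
known ground truth: analytic Hessians of harmonic bond/angle force fields,
exact Coulomb ESP grids outside 1.4x the van der Waals surface, exact
cosine-series torsion profiles, isotropic Gaussian jitter trajectories, and
Crooks-consistent Gaussian work pairs (forward ~ N(ΔG + σ²/2, σ²),
backward ~ N(−ΔG + σ²/2, σ²)). Each generator draws from its own stream
seeded explicitly and restores the global RNG state.

Passing these oracles shows the implementations are correct for inputs
inside their model class. It does not show that real QM Hessians are
harmonic (they are not — anharmonicity and inter-term coupling are why
uncorrected angle constants overshoot), that real ESP fields are
point-charge-representable, that real work distributions are Gaussian, or
that real trajectories fluctuate isotropically. The fixtures validate the
estimators, not the physics of any particular system.

Test problem sizes are the package's choices for a fast, convincing suite:
BAR recovery uses 1e5 work samples per direction (so the ±0.02 kT check
sits at roughly nine standard errors), RMSF uses a 60-atom polypeptide over
1000 frames — with N atoms, superposition removes a 6/(3N) fraction of the
jitter variance, so small fixtures would bias the √3·σ comparison by more
than the 5% band — and RESP grids use 100+ points per atom.

## Known limitations

* Heavy atoms only; protonation and hydrogen placement are delegated to
  external tools (an interface stub, not implemented here).
* No ring-closure or chirality repair after editing; proline's ring is
  approximate at the template level.
* Rotamer selection counts clashes only — no rotamer statistics and no
  hydrogen-bond term.
* Parameter derivation covers bonded terms and charges; Lennard-Jones
  parameters are inherited from the base force field, and the bulky
  glutathionyl/cystine products get no special conformer optimization
  beyond the generic chi scan.
* Network fetching of structures by database id is out of scope; readers
  take local files or text.
* Binary trajectory formats are not parsed; trajectories enter as in-memory
  arrays or whitespace-delimited tables.
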