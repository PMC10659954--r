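# ptmforge

Post-translational modifications (PTMs) — especially redox modifications of
cysteine thiols such as S-nitrosylation — change how a protein folds, moves
and binds its ligands, but the modified residues are missing from standard
biomolecular force fields. `ptmforge` is an R toolkit for the desk-side part
of that problem: it edits PTMs into protein structures in silico, derives
force-field parameters for the resulting non-standard residues from
quantum-chemistry data, plans the surrounding molecular-dynamics and docking
workflow as text artifacts, and analyzes the alchemical free-energy and
contact statistics that come back. It never runs a QM or MD engine itself;
seeded synthetic-fixture generators stand in for engine output so every
numerical method is testable on a laptop.

## What is inside

**Structure editing.** A hierarchical `Protein > Chain > Residue > atoms`
model with fixed-column PDB I/O and `"A:CYS155"`-style site addressing.
Residues are built in internal coordinates and converted to Cartesian
positions with the Natural Extension of Reference Frame (NERF) algorithm;
fragments are aligned with a quaternion least-squares superposition.
`mutate()` swaps a residue for any of the bundled standard or PTM templates
(SNC, CSS, SMC, XCN, CSO, CSD, OCS, QCS, CGL, IYY) keeping the backbone
fixed; `modify()` applies a named chemical reaction from the bundled
(residue, reaction) registry, e.g. `modify(p, "A:CYS1", "nitrosylation")`.
Steric clashes trigger a deterministic rotamer search over the side-chain
torsions chi1/chi2 in 30-degree increments; if no clash-free rotamer exists
the least-clash conformation is kept with a warning.

**Force-field parameterization.** For a non-standard residue in its capped
ACE-XXX-NME dipeptide:

* harmonic bond and angle constants from QM Hessians by the modified
  Seminario method — the interatomic 3x3 sub-blocks of −H are projected by
  singular value decomposition, `kb = Σ σ_m |v_m·û|²` along the unit bond
  vector, and the bending constant comes from the 1–3 sub-block projected
  onto the two in-plane perpendicular vectors, with a geometric correction
  for angles sharing a central atom;
* multi-conformational RESP charges: least-squares reproduction of the
  electrostatic potential across the alpha-helix and beta-strand conformers
  under hyperbolic restraints (`a (√(q²+b²) − b)`), hard total-charge and
  capping-group constraints, and the two-stage refit with methyl/methylene
  equivalences;
* torsion series `V(φ) = Σ k_φ (1 + cos(nφ − φ_s))` fitted linearly to
  QM-minus-baseline energy profiles with phases restricted to {0, 180};
* emission and re-parsing of GROMACS-dialect residue/bonded include files.

The complete published parameter set for S-nitroso-L-cysteine (SNC) —
charges, bonds, angles, torsions — ships with the package
(`bundled_snc_parameters()`).

**Workflow planning.** Pure text generators for: two-stage thermodynamic
integration schedules (13-step lambda ladder per stage, shared fully-coupled
state, 25 one-ns legs), equilibration protocols (dodecahedron box with 1 nm
buffer, 1000/500/200/100/10/5/1 restraint ladder, 500 ps NVT, 20 ns
unrestrained NPT), SLTCAP ion counts excluding the protein volume, QM decks
for both dipeptide conformers, torsion-fit configurations (dihedral
restraint ≥ 14,000 kJ mol⁻¹ rad⁻², positional restraint 418 kJ mol⁻¹ nm⁻²),
docking configurations (exhaustiveness 64, two-ligand boxes clamped to at
least 19 x 27 x 16 Å), and scheduler batch scripts.

**Analysis.** Persistent close contacts (any atom within 0.35 nm of the
site residue in ≥ 70% of frames, peptide-bonded neighbours excluded), RMSF
after superposition onto the mean structure, and free energies from
forward/backward work samples via Bennett's acceptance ratio (BAR), with
per-leg chaining into stage subtotals.

## Worked example

```r
library(ptmforge)

# build a cysteine, S-nitrosylate it
snc <- prepend_residue(ptm_protein(), "A", "CYS")
snc <- modify(snc, "A:CYS1", "nitrosylation")
find_residue(snc, "A:SNC1")$atoms[, c("name", "element")]
#>   name element      (N, CA, C, O, CB, SG + the new ND, OE of the S-N=O group)

pars <- bundled_snc_parameters()
cat("S-N bond: req =", pars$bonds[[2]]$req, "nm, kb =", pars$bonds[[2]]$kb, "\n")
#> S-N bond: req = 0.1918 nm, kb = 79743.2

sched <- gen_ti_schedule()
cat(nrow(sched$legs), "legs,", length(sched$stages[[1]]), "lambdas per stage\n")
#> 25 legs, 13 lambdas per stage

# BAR on synthetic Crooks-consistent work with true dG = 1 kT
est <- bar_delta_g(make_gaussian_work(1, sigma2 = 1, n = 1e5, seed = 1))
sprintf("%.3f +/- %.3f kT", est$delta_g, est$se)
#> "0.998 +/- 0.002 kT"

# ions for a -8 e protein in 0.15 M salt, 1000 nm^3 of water
plan <- sltcap_ion_counts(-8, 0.15, 1000)
c(plan$n_cations, plan$n_anions)
#> 94 86
```

The S-N bond of the built residue measures 1.918 Å with a C-S-N angle of
99.5 degrees and an S-N-O angle of 117.2 degrees — the equilibrium geometry
of the bundled parameter set. The ion plan is exactly neutralizing
(94 − 86 = 8) and satisfies the SLTCAP identity N₊N₋ = N₀².

A thin CLI over the same functions is installed at `exec/ptmforge`
(`convert`, `mutate`, `modify`, `cap`, `list-modifications`).

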