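# Deterministic generation of the text artifacts the workflow delegates to
# external engines: QM input decks, MD equilibration protocols, TI lambda
# schedules, torsion-fit configurations, docking configurations, and batch
# scripts. Generators are pure: identical inputs give byte-identical text.
# Nothing here is ever executed by the package.

# every numeric default lives in exactly this one table
.wf_defaults <- list(
  ti_lambdas = c(0.00, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
                 0.60, 0.70, 0.80, 0.90, 0.95, 1.00),
  ti_leg_ns = 1,
  box_type = "dodecahedron",
  box_buffer_nm = 1,
  minimization_ladder = c(1000, 500, 200, 100, 10, 5, 1),  # kJ mol-1 nm-2
  nvt_ps = 500,
  nvt_temperature_K = 300,
  npt_unrestrained_ns = 20,
  npt_pressure_atm = 1,
  timestep_fs = 2,
  salt_mol_per_L = 0.15,
  dihedral_restraint = 14000,   # kJ mol-1 rad-2
  position_restraint = 418,     # kJ mol-1 nm-2
  exhaustiveness = 64,
  min_box_two_ligands = c(19, 27, 16),  # Angstrom
  qm_functional = "r2SCAN-D3(BJ)",
  qm_orbital_basis = "def2-TZVP",
  qm_fitting_basis = "def2-universal-jfit",
  qm_grid = "lebedev 120 41",
  esp_method = "HF",
  esp_basis = "6-31G*",
  alpha_phi_psi = c(-60, -45),
  beta_phi_psi = c(-135, 135),
  scheduler_partition = "normal",
  scheduler_time = "12:00:00",
  scheduler_nodes = 1
)

#' Default workflow settings
#' @return Named list of every numeric/text default used by the generators.
#' @export
workflow_defaults <- function() .wf_defaults

#' Generate a two-stage thermodynamic-integration schedule
#'
#' The alchemical decoupling runs in two stages, electrostatic first, then
#' van der Waals together with masses and bonded terms, each over the
#' default 13-value lambda ladder from 0.00 (modified residue) to 1.00
#' (regular residue). The fully coupled boundary state is shared between the
#' stages, so the default flattened plan has 25 one-nanosecond legs.
#'
#' @param lambdas Ascending lambda values in [0, 1], starting at 0 and
#'   ending at 1; default the published 13-step ladder.
#' @param stages Stage labels, in decoupling order.
#' @param leg_ns Duration of each leg, ns.
#' @return A `ti_schedule`: list with `stages` (per-stage lambda lists),
#'   `legs` (data frame stage/lambda), `leg_ns`.
#' @export
gen_ti_schedule <- function(lambdas = .wf_defaults$ti_lambdas,
                            stages = c("electrostatic", "vdw-bonded"),
                            leg_ns = .wf_defaults$ti_leg_ns) {
  lambdas <- as.numeric(lambdas)
  if (is.unsorted(lambdas, strictly = TRUE)) {
    stop("lambda list must be strictly increasing")
  }
  if (abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12) {
    stop("lambda list must start at 0.00 and end at 1.00")
  }
  legs <- data.frame(stage = character(0), lambda = numeric(0))
  for (s in seq_along(stages)) {
    lam <- lambdas
    if (s > 1) lam <- lam[-1]   # shared fully-coupled boundary state
    legs <- rbind(legs, data.frame(stage = stages[s], lambda = lam))
  }
  structure(list(stages = stats::setNames(rep(list(lambdas), length(stages)), stages),
                 legs = legs, leg_ns = leg_ns),
            class = "ti_schedule")
}

#' Generate an equilibration protocol and engine script
#'
#' Standard protocol: solvation in a dodecahedron box (1 nm buffer),
#' SLTCAP-based neutralization/salting, a strictly decreasing restrained
#' minimization ladder, restrained NVT thermalization, and an unrestrained
#' NPT equilibration (20 ns default). The returned script is an ordered list
#' of engine commands as text; nothing is executed.
#'
#' @param protein A `ptm_protein` (used for charge/volume bookkeeping in the
#'   ion step); may be `NULL` for a generic template.
#' @param box_buffer_nm,npt_ns,nvt_ps,temperature_K,timestep_fs,salt_mol_per_L
#'   Overrides of the named defaults.
#' @param ladder Minimization restraint ladder, kJ mol-1 nm-2, strictly
#'   decreasing.
#' @param protein_charge Net charge used for the ion step.
#' @return An `md_protocol`: list with the settings and a `script` character
#'   vector.
#' @export
gen_equilibration_protocol <- function(protein = NULL,
                                       box_buffer_nm = .wf_defaults$box_buffer_nm,
                                       npt_ns = .wf_defaults$npt_unrestrained_ns,
                                       nvt_ps = .wf_defaults$nvt_ps,
                                       temperature_K = .wf_defaults$nvt_temperature_K,
                                       timestep_fs = .wf_defaults$timestep_fs,
                                       salt_mol_per_L = .wf_defaults$salt_mol_per_L,
                                       ladder = .wf_defaults$minimization_ladder,
                                       protein_charge = 0) {
  if (any(diff(ladder) >= 0)) stop("minimization ladder must be strictly decreasing")
  if (box_buffer_nm <= 0 || npt_ns <= 0 || nvt_ps <= 0 || timestep_fs <= 0) {
    stop("durations and box buffer must be positive")
  }
  # ion bookkeeping: box estimated from the protein when available
  vol_note <- ""
  ions <- NULL
  if (!is.null(protein)) {
    vp <- protein_volume(protein)
    # crude bounding estimate of the image distance: protein diameter + 2*buffer
    at <- protein_atoms(protein)
    diam <- if (nrow(at)) max(dist(as.matrix(at[, c("x", "y", "z")]))) * 0.1 else 0
    vbox <- box_volume(diam + 2 * box_buffer_nm, .wf_defaults$box_type)
    ions <- sltcap_ion_counts(protein_charge, salt_mol_per_L,
                              max(vbox - vp, 1e-6))
    vol_note <- sprintf(" (protein volume %.3f nm^3 excluded)", vp)
  }
  script <- c(
    "# equilibration protocol (engine commands; text only)",
    sprintf("editconf -bt %s -d %g", .wf_defaults$box_type, box_buffer_nm),
    "solvate -cs tip3p",
    if (!is.null(ions)) sprintf("genion -np %d -nn %d  # SLTCAP at %g mol/L%s",
                                ions$n_cations, ions$n_anions, salt_mol_per_L,
                                vol_note)
    else sprintf("genion  # SLTCAP at %g mol/L", salt_mol_per_L),
    sprintf("minimize -posre %g", ladder),
    sprintf("nvt -t %g -ps %g -dt %gfs", temperature_K, nvt_ps, timestep_fs),
    sprintf("npt -t %g -ns %g -dt %gfs  # unrestrained", temperature_K, npt_ns,
            timestep_fs)
  )
  structure(list(box = list(type = .wf_defaults$box_type, buffer_nm = box_buffer_nm),
                 minimization_ladder = ladder,
                 nvt = list(ps = nvt_ps, temperature_K = temperature_K),
                 npt = list(ns = npt_ns, pressure_atm = .wf_defaults$npt_pressure_atm),
                 timestep_fs = timestep_fs, ions = ions, script = script),
            class = "md_protocol")
}

#' Generate QM input decks for residue parameterization
#'
#' Produces, for both the alpha-helix (phi, psi = -60, -45) and beta-strand
#' (-135, 135) conformers of the capped ACE-XXX-NME dipeptide: a geometry
#' optimization + Hessian deck annotated with the default density-functional
#' setup, an ESP deck annotated with the Hartree-Fock/6-31G* setup and the
#' capping-group charge constraints, and a torsion-scan deck that freezes
#' phi, psi and the scanned dihedral.
#'
#' @param residue_code Residue in the template library.
#' @param scan_dihedral Character quadruple of atom names for the scanned
#'   torsion (default the first side-chain torsion of the SNC-style chi2).
#' @return A `qm_deck_set`: list of conformers, each with `phi_psi` and deck
#'   texts `geometry`, `esp`, `scan`.
#' @export
gen_qm_decks <- function(residue_code,
                         scan_dihedral = c("CA", "CB", "SG", "ND")) {
  tpl <- residue_template(residue_code)   # errors for unknown residues
  conformers <- list(alpha = .wf_defaults$alpha_phi_psi,
                     beta = .wf_defaults$beta_phi_psi)
  decks <- lapply(names(conformers), function(cf) {
    pp <- conformers[[cf]]
    dip <- build_dipeptide(tpl$code, cf)
    geom <- c(sprintf("# geometry + hessian deck: ACE-%s-NME, %s conformer",
                      tpl$code, cf),
              sprintf("# phi/psi frozen at (%g, %g)", pp[1], pp[2]),
              sprintf("theory dft xc %s", .wf_defaults$qm_functional),
              sprintf("basis orbital %s", .wf_defaults$qm_orbital_basis),
              sprintf("basis fitting %s", .wf_defaults$qm_fitting_basis),
              sprintf("grid %s", .wf_defaults$qm_grid),
              "task optimize", "task hessian",
              "geometry angstrom",
              write_pdb(dip))
    esp <- c(sprintf("# esp deck: ACE-%s-NME, %s conformer", tpl$code, cf),
             sprintf("theory %s basis %s", .wf_defaults$esp_method,
                     .wf_defaults$esp_basis),
             "esp grid chelpg",
             "constrain group ACE total 0.0",
             "constrain group NME total 0.0",
             "task esp")
    scan <- c(sprintf("# torsion scan deck: ACE-%s-NME, %s conformer", tpl$code, cf),
              sprintf("freeze dihedral phi %g", pp[1]),
              sprintf("freeze dihedral psi %g", pp[2]),
              sprintf("freeze dihedral scan %s", paste(scan_dihedral, collapse = "-")),
              "scan -180 180 step 15", "task optimize")
    list(conformer = cf, phi_psi = pp, geometry = geom, esp = esp, scan = scan)
  })
  names(decks) <- names(conformers)
  structure(list(residue = tpl$code, conformers = decks), class = "qm_deck_set")
}

#' Generate a torsion-fit configuration
#'
#' The fit configuration restrains the three frozen dihedrals (phi, psi and
#' the scanned angle) with a force constant of at least 14,000 kJ mol-1
#' rad-2 and weakly restrains all other atomic positions with 418 kJ mol-1
#' nm-2, allowing orthogonal relaxation while staying close to the QM scan.
#'
#' @param profiles A `torsion_profile` or list of them.
#' @param dihedral_restraint Dihedral restraint, kJ mol-1 rad-2 (>= 14000 by
#'   default).
#' @param position_restraint Positional restraint, kJ mol-1 nm-2.
#' @return A `torsion_fit_config`: list with the restraints and a `text`
#'   character vector.
#' @export
gen_torsion_fit_config <- function(profiles,
                                   dihedral_restraint = .wf_defaults$dihedral_restraint,
                                   position_restraint = .wf_defaults$position_restraint) {
  if (inherits(profiles, "torsion_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one torsion profile")
  dihs <- vapply(profiles, function(p) paste(p$atoms, collapse = "-"), "")
  text <- c("# torsion fitting configuration",
            sprintf("target dihedral %s", unique(dihs)),
            sprintf("restraint dihedral %g  # kJ mol-1 rad-2", dihedral_restraint),
            sprintf("restraint position %g  # kJ mol-1 nm-2", position_restraint),
            sprintf("profiles %d", length(profiles)))
  structure(list(dihedral_restraint = dihedral_restraint,
                 position_restraint = position_restraint,
                 dihedrals = unique(dihs), text = text),
            class = "torsion_fit_config")
}

#' Generate a docking configuration
#'
#' Defaults to exhaustiveness 64. When two or more ligands are supplied
#' (multiple-ligand docking), the search-box lengths are floor-clamped to
#' (19, 27, 16) Angstrom so that both ligands fit. Without a box and without
#' an annotated binding site on the receptor, configuration fails: the user
#' must supply the box parameters.
#'
#' @param receptor Receptor reference (path or label); may carry an
#'   annotated site as `attr(receptor, "site")` = list(center =, size =).
#' @param ligands Character vector of ligand references.
#' @param box Optional list with `center` (3-vector, Angstrom) and `size`
#'   (3 lengths, Angstrom).
#' @param exhaustiveness Search exhaustiveness.
#' @param scoring Scoring function name.
#' @return A `docking_config`: list with the settings and a `text` character
#'   vector.
#' @export
gen_docking_config <- function(receptor, ligands, box = NULL,
                               exhaustiveness = .wf_defaults$exhaustiveness,
                               scoring = "vina") {
  if (is.null(box)) {
    site <- attr(receptor, "site")
    if (is.null(site)) {
      stop("no search box supplied and the receptor has no annotated binding ",
           "site; the user must supply the box parameters (size and center)")
    }
    box <- site
  }
  if (any(box$size <= 0)) stop("box lengths must be positive")
  multi <- length(ligands) >= 2
  if (multi) box$size <- pmax(box$size, .wf_defaults$min_box_two_ligands)
  text <- c(sprintf("receptor = %s", as.character(receptor)),
            sprintf("ligand = %s", ligands),
            sprintf("center_x = %g", box$center[1]),
            sprintf("center_y = %g", box$center[2]),
            sprintf("center_z = %g", box$center[3]),
            sprintf("size_x = %g", box$size[1]),
            sprintf("size_y = %g", box$size[2]),
            sprintf("size_z = %g", box$size[3]),
            sprintf("exhaustiveness = %d", as.integer(exhaustiveness)),
            sprintf("scoring = %s", scoring))
  structure(list(receptor = as.character(receptor), ligands = ligands,
                 box = box, exhaustiveness = as.integer(exhaustiveness),
                 scoring = scoring, multi_ligand = multi, text = text),
            class = "docking_config")
}

#' Generate a batch submission script
#'
#' Wraps any generated artifact's command list in a portable shell script
#' with scheduler directives. Every option is overridable; output is
#' deterministic for fixed inputs.
#'
#' @param commands Character vector of shell commands (e.g. the `script`
#'   field of [gen_equilibration_protocol()]).
#' @param job_name,partition,time,nodes Scheduler options.
#' @param scheduler `"slurm"` or `"none"` (plain script, no directives).
#' @return Character scalar: the script text.
#' @export
gen_batch_script <- function(commands = character(0), job_name = "ptm-workflow",
                             partition = .wf_defaults$scheduler_partition,
                             time = .wf_defaults$scheduler_time,
                             nodes = .wf_defaults$scheduler_nodes,
                             scheduler = c("slurm", "none")) {
  scheduler <- match.arg(scheduler)
  header <- c("#!/bin/bash")
  if (scheduler == "slurm") {
    header <- c(header,
                sprintf("#SBATCH --job-name=%s", job_name),
                sprintf("#SBATCH --partition=%s", partition),
                sprintf("#SBATCH --time=%s", time),
                sprintf("#SBATCH --nodes=%d", as.integer(nodes)))
  }
  paste0(paste(c(header, "", commands), collapse = "\n"), "\n")
}

#' Generate a structural-inference placeholder script
#'
#' Emits a documented placeholder for the sequence-to-structure inference
#' pipeline (virtual environment, dependency install, container pull,
#' inference, copy-back) as comments plus a stub command. The pipeline is
#' never executed by this package.
#'
#' @param fasta Character vector of FASTA paths or sequences.
#' @return Character scalar: the script text.
#' @export
gen_inference_script <- function(fasta) {
  body <- c("# structural inference pipeline (placeholder; not executed):",
            "#   1. create a Python virtual environment",
            "#   2. install dependencies",
            "#   3. pull the inference container",
            "#   4. run inference on the input sequences",
            "#   5. copy results back to the submission directory",
            sprintf("run_inference %s", paste(fasta, collapse = " ")))
  gen_batch_script(body, job_name = "structure-inference")
}
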