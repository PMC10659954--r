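# Force-field parameter derivation for non-standard residues:
# modified Seminario bond/angle constants from QM Hessians (SVD projection),
# multi-conformational RESP charges, cosine-series torsion fitting, closed
# form term evaluation, and GROMACS-dialect include-file emission.
#
# Units at this layer are GROMACS-native: nm, kJ mol-1, degrees for angles
# and phases, kJ mol-1 rad-2 for bending constants. Structure-layer
# coordinates (Angstrom) are converted at the boundary.

ANG2NM <- 0.1

#' Harmonic bond term
#' @param atoms Character pair of atom names.
#' @param req Equilibrium length, nm (> 0).
#' @param kb Force constant, kJ mol-1 nm-2 (>= 0).
#' @return A `bond_term`; energy is V(r) = 1/2 kb (r - req)^2.
#' @export
bond_term <- function(atoms, req, kb) {
  stopifnot(length(atoms) == 2, req > 0, kb >= 0)
  structure(list(atoms = as.character(atoms), req = req, kb = kb),
            class = "bond_term")
}

#' Harmonic angle term
#' @param atoms Character triple of atom names.
#' @param theta_eq Equilibrium angle, degrees in (0, 180).
#' @param k_theta Force constant, kJ mol-1 rad-2 (>= 0).
#' @param corrected Logical: was the shared-central-atom geometric
#'   correction applicable (any sibling angle at the same center)?
#' @return An `angle_term`; energy is V(theta) = 1/2 k (theta - theta_eq)^2
#'   with theta in radians.
#' @export
angle_term <- function(atoms, theta_eq, k_theta, corrected = FALSE) {
  stopifnot(length(atoms) == 3, theta_eq > 0, theta_eq < 180, k_theta >= 0)
  structure(list(atoms = as.character(atoms), theta_eq = theta_eq,
                 k_theta = k_theta, corrected = corrected),
            class = "angle_term")
}

#' Cosine torsion series
#' @param atoms Character quadruple of atom names.
#' @param terms Data frame with columns `k_phi` (kJ mol-1), `n` (positive
#'   integer multiplicity) and `phi_s` (phase, degrees; 0 or 180 unless
#'   overridden).
#' @return A `torsion_series`; energy is
#'   V(phi) = sum k_phi (1 + cos(n phi - phi_s)).
#' @export
torsion_series <- function(atoms, terms) {
  stopifnot(length(atoms) == 4)
  terms <- as.data.frame(terms)
  stopifnot(all(c("k_phi", "n", "phi_s") %in% names(terms)))
  if (nrow(terms) && any(terms$n < 1)) stop("multiplicity n must be >= 1")
  structure(list(atoms = as.character(atoms), terms = terms),
            class = "torsion_series")
}

#' Bundle of QM second derivatives for one conformer
#'
#' @param conformer Label, `"alpha"` or `"beta"`.
#' @param positions Nx3 matrix, Angstrom, with atom names as rownames (or
#'   supply `atom_names`).
#' @param hessian 3Nx3N matrix of energy second derivatives with respect to
#'   nm displacements, kJ mol-1 nm-2; must be symmetric to 1e-6 relative.
#' @param atom_names Optional character vector of atom names.
#' @return A `hessian_bundle`.
#' @export
hessian_bundle <- function(conformer, positions, hessian, atom_names = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, nrow(hessian) == 3 * n, ncol(hessian) == 3 * n)
  asym <- max(abs(hessian - t(hessian)))
  if (asym > 1e-6 * max(abs(hessian), 1)) {
    stop("Hessian is not symmetric (relative asymmetry ",
         signif(asym / max(abs(hessian)), 3), ")")
  }
  if (is.null(atom_names)) atom_names <- rownames(positions)
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(n))
  structure(list(conformer = conformer, positions = positions,
                 hessian = hessian, atom_names = atom_names),
            class = "hessian_bundle")
}

# 3x3 interatomic sub-block of -H for atoms (i, j)
.hess_block <- function(h, i, j) {
  ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
  -h$hessian[ri, rj]
}

.bundle_list <- function(h) {
  if (inherits(h, "hessian_bundle")) list(h) else h
}

#' Bond force constant from QM Hessians (modified Seminario, SVD)
#'
#' The stretching constant is obtained from the 3x3 interatomic sub-block
#' -d2E/dri drj by singular value decomposition, summing sigma_m |v_m . u|^2
#' over the singular triples with u the unit bond vector (the SVD avoids the
#' complex eigenvalues a non-symmetric sub-block can have, at the price of
#' slightly stiffer constants). The equilibrium length is the current
#' distance. With several conformer bundles, constants and lengths are
#' arithmetic means (equal weights; order-independent).
#'
#' @param h A `hessian_bundle` or list of bundles (e.g. alpha and beta
#'   conformers).
#' @param i,j Atom indices (i != j), expected to be bonded.
#' @return A [bond_term()] (req in nm, kb in kJ mol-1 nm-2).
#' @export
seminario_bond <- function(h, i, j) {
  stopifnot(i != j)
  hs <- .bundle_list(h)
  ks <- reqs <- numeric(0)
  for (b in hs) {
    M <- .hess_block(b, i, j)
    if (sqrt(sum(M^2)) < 1e-8) {
      stop("degenerate Hessian: near-zero interatomic sub-block for atoms ",
           i, "-", j)
    }
    rij <- (b$positions[i, ] - b$positions[j, ]) * ANG2NM
    req <- sqrt(sum(rij^2))
    u <- rij / req
    s <- svd(M)
    ks <- c(ks, sum(s$d * as.numeric(crossprod(s$v, u))^2))
    reqs <- c(reqs, req)
  }
  nm <- c(hs[[1]]$atom_names[i], hs[[1]]$atom_names[j])
  bond_term(nm, req = mean(reqs), kb = mean(ks))
}

# in-plane perpendicular unit vectors of angle i-j-k at positions (nm or A)
.angle_frame <- function(pos, i, j, k) {
  u_ij <- pos[i, ] - pos[j, ]; R1 <- sqrt(sum(u_ij^2)); u_ij <- u_ij / R1
  u_kj <- pos[k, ] - pos[j, ]; R2 <- sqrt(sum(u_kj^2)); u_kj <- u_kj / R2
  n <- .cross3(u_kj, u_ij)
  if (sqrt(sum(n^2)) < 1e-8) stop("collinear atoms ", i, "-", j, "-", k)
  n <- n / sqrt(sum(n^2))
  list(u_ij = u_ij, u_kj = u_kj, R1 = R1, R2 = R2,
       u_pa = .cross3(n, u_ij), u_pc = .cross3(u_kj, n),
       theta = .rad2deg(acos(max(-1, min(1, sum(u_ij * u_kj))))))
}

#' Angle force constant from QM Hessians (modified Seminario, SVD)
#'
#' The bending constant for angle i-j-k is obtained by projecting the 1-3
#' interatomic sub-block -d2E/dri drk onto the two in-plane unit vectors
#' perpendicular to the i-j and k-j bonds:
#' k_theta = R_ij R_kj sum sigma_m |u_m . u_Pi| |v_m . u_Pk|. When sibling
#' angles share the central atom j, the geometric correction divides each
#' bond-side contribution by 1 + sum of squared overlaps of the
#' perpendicular vectors of siblings sharing that bond (angles with no
#' sibling at their center are returned unchanged and flagged uncorrected,
#' and remain prone to overestimation). Conformer averaging as for bonds.
#'
#' @param h A `hessian_bundle` or list of bundles.
#' @param i,j,k Atom indices; i-j and j-k are the bonded arms.
#' @param angles Optional matrix/data frame (rows of atom-index triples) of
#'   all angles in the molecule, used to find siblings sharing center j.
#' @return An [angle_term()] (theta_eq degrees, k_theta kJ mol-1 rad-2).
#' @export
seminario_angle <- function(h, i, j, k, angles = NULL) {
  hs <- .bundle_list(h)
  sib <- list()
  if (!is.null(angles)) {
    angles <- as.matrix(angles)
    for (r in seq_len(nrow(angles))) {
      tr <- as.integer(angles[r, ])
      if (tr[2] == j && !(tr[1] == i && tr[3] == k) && !(tr[1] == k && tr[3] == i)) {
        sib[[length(sib) + 1L]] <- tr
      }
    }
  }
  ks <- ths <- numeric(0)
  for (b in hs) {
    pos_nm <- b$positions * ANG2NM
    fr <- .angle_frame(pos_nm, i, j, k)
    M <- .hess_block(b, i, k)
    if (sqrt(sum(M^2)) < 1e-10) {
      stop("degenerate Hessian: near-zero 1-3 sub-block for atoms ", i, "-", k)
    }
    s <- svd(M)
    k_raw <- fr$R1 * fr$R2 *
      sum(s$d * abs(as.numeric(crossprod(s$u, fr$u_pa))) *
            abs(as.numeric(crossprod(s$v, fr$u_pc))))
    # shared-central-atom correction: scale each arm by the perpendicular
    # overlap with siblings that share that arm's bond
    N1 <- N2 <- 1
    for (tr in sib) {
      outer_atoms <- tr[c(1, 3)]
      for (arm in 1:2) {
        arm_outer <- if (arm == 1) i else k
        if (arm_outer %in% outer_atoms) {
          other <- setdiff(outer_atoms, arm_outer)[1]
          fr2 <- tryCatch(.angle_frame(pos_nm, arm_outer, j, other),
                          error = function(e) NULL)
          if (is.null(fr2)) next
          upa <- if (arm == 1) fr$u_pa else fr$u_pc
          ov <- sum(upa * fr2$u_pa)^2
          if (arm == 1) N1 <- N1 + ov else N2 <- N2 + ov
        }
      }
    }
    ks <- c(ks, 2 * k_raw / (N1 + N2))
    ths <- c(ths, fr$theta)
  }
  nm <- hs[[1]]$atom_names[c(i, j, k)]
  angle_term(nm, theta_eq = mean(ths), k_theta = mean(ks),
             corrected = length(sib) > 0)
}

# ---- RESP charge fitting ------------------------------------------------

#' Electrostatic-potential sample for one conformer
#'
#' @param conformer Label.
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param grid Px3 matrix of sample-point positions, Angstrom.
#' @param esp Length-P vector of electrostatic potential values in e/Angstrom
#'   (Coulomb constant 1).
#' @return An `esp_sample`. Requires at least 10 grid points per atom.
#' @export
esp_sample <- function(conformer, atoms, grid, esp) {
  grid <- as.matrix(grid)
  stopifnot(ncol(grid) == 3, length(esp) == nrow(grid))
  if (nrow(grid) < 10 * nrow(atoms)) {
    stop("need at least 10 grid points per atom (got ", nrow(grid), " for ",
         nrow(atoms), " atoms)")
  }
  structure(list(conformer = conformer, atoms = atoms, grid = grid,
                 esp = as.numeric(esp)), class = "esp_sample")
}

#' Multi-conformational RESP charge fit
#'
#' Minimizes the summed squared ESP error across all supplied conformers
#' (equal weights) plus the hyperbolic restraint
#' a * sum(sqrt(q^2 + b^2) - b) on non-hydrogen atoms, subject to hard
#' linear constraints (total charge; optional fixed-total groups such as the
#' capping-group charges of the parameterization dipeptide, and optional
#' equivalence classes). The default two-stage recipe refits
#' methyl/methylene-type atoms with equivalences at a stronger restraint in
#' a second pass, all other charges frozen.
#'
#' @param samples An `esp_sample` or list of them (conformers of the same
#'   molecule; atom rosters must match).
#' @param constraints List of `list(atoms =, total =)` fixed-total groups
#'   (atom names or indices).
#' @param total_charge Net molecular charge (e).
#' @param restraint_a Stage-1 hyperbolic restraint strength (0 disables).
#' @param restraint_b Hyperbolic restraint width.
#' @param stage2_atoms Optional atom names/indices refit in stage 2.
#' @param stage2_equiv Optional list of atom-name/index groups constrained
#'   equal in stage 2.
#' @param stage2_a Stage-2 restraint strength.
#' @return A `charge_set`: list with `charges` (named, e), `rrms` (relative
#'   root-mean-square ESP error) and `total` (sum of charges).
#' @export
resp_fit <- function(samples, constraints = list(), total_charge = 0,
                     restraint_a = 0.0005, restraint_b = 0.1,
                     stage2_atoms = NULL, stage2_equiv = NULL,
                     stage2_a = 0.001) {
  if (inherits(samples, "esp_sample")) samples <- list(samples)
  if (!length(samples)) stop("need at least one conformer sample")
  atoms <- samples[[1]]$atoms
  n <- nrow(atoms)
  idx_of <- function(x) {
    if (is.character(x)) {
      i <- match(x, atoms$name)
      if (anyNA(i)) stop("unknown atom name(s): ", paste(x[is.na(i)], collapse = ", "))
      i
    } else as.integer(x)
  }
  A <- NULL; b <- NULL
  for (s in samples) {
    if (nrow(s$atoms) != n) stop("conformer atom rosters differ")
    D <- matrix(0, nrow(s$grid), n)
    for (a in seq_len(n)) {
      d <- sqrt(rowSums(sweep(s$grid, 2, as.numeric(s$atoms[a, c("x", "y", "z")]))^2))
      D[, a] <- 1 / d
    }
    A <- rbind(A, D); b <- c(b, s$esp)
  }
  heavy <- toupper(atoms$element) != "H"

  solve_stage <- function(a_rstr, frozen = NULL, equiv = list()) {
    # parameter mapping for equivalences and frozen atoms
    par_of <- seq_len(n)
    for (g in equiv) {
      g <- idx_of(g)
      par_of[g] <- min(par_of[g])
    }
    if (!is.null(frozen)) par_of[frozen$idx] <- 0L
    free_pars <- sort(unique(par_of[par_of > 0L]))
    P <- matrix(0, n, length(free_pars))
    for (a in seq_len(n)) {
      if (par_of[a] > 0L) P[a, match(par_of[a], free_pars)] <- 1
    }
    rhs_fix <- rep(0, n)
    if (!is.null(frozen)) rhs_fix[frozen$idx] <- frozen$values
    Af <- A %*% P
    bf <- b - A %*% rhs_fix
    # constraints in reduced space
    Cm <- matrix(1, 1, n); dv <- total_charge
    for (g in constraints) {
      row <- rep(0, n); row[idx_of(g$atoms)] <- 1
      Cm <- rbind(Cm, row); dv <- c(dv, g$total)
    }
    Cr <- Cm %*% P
    dr <- dv - as.numeric(Cm %*% rhs_fix)
    keep <- qr(t(Cr))$rank
    if (keep < nrow(Cr)) {
      # drop dependent rows; verify consistency
      qq <- qr(t(Cr))
      sel <- sort(qq$pivot[seq_len(keep)])
      sol_try <- tryCatch(qr.solve(Cr[sel, , drop = FALSE], dr[sel]),
                          error = function(e) NULL)
      if (is.null(sol_try) || max(abs(Cr %*% sol_try - dr)) > 1e-8) {
        stop("infeasible charge constraints")
      }
      Cr <- Cr[sel, , drop = FALSE]; dr <- dr[sel]
    }
    npar <- ncol(Af); ncon <- nrow(Cr)
    AtA <- crossprod(Af); Atb <- crossprod(Af, bf)
    q <- rep(0, npar)
    for (iter in seq_len(200)) {
      pen <- rep(0, n)
      if (a_rstr > 0) {
        qa <- as.numeric(P %*% q) + rhs_fix
        pen <- ifelse(heavy, a_rstr / sqrt(qa^2 + restraint_b^2), 0)
      }
      Dm <- crossprod(P, P * pen)
      K <- rbind(cbind(AtA + Dm, t(Cr)),
                 cbind(Cr, matrix(0, ncon, ncon)))
      if (qr(K)$rank < nrow(K)) {
        stop("rank-deficient RESP design; supply more grid points or fewer equivalences")
      }
      sol <- solve(K, c(Atb, dr))
      qn <- sol[seq_len(npar)]
      if (max(abs(qn - q)) < 1e-12) { q <- qn; break }
      q <- qn
      if (a_rstr == 0) break
    }
    as.numeric(P %*% q) + rhs_fix
  }

  q1 <- solve_stage(restraint_a)
  q <- q1
  if (!is.null(stage2_atoms)) {
    s2 <- idx_of(stage2_atoms)
    frozen_idx <- setdiff(seq_len(n), s2)
    q <- solve_stage(stage2_a,
                     frozen = list(idx = frozen_idx, values = q1[frozen_idx]),
                     equiv = if (is.null(stage2_equiv)) list() else stage2_equiv)
  }
  pred <- as.numeric(A %*% q)
  rrms <- sqrt(sum((pred - b)^2) / max(sum(b^2), .Machine$double.eps))
  total <- sum(q)
  if (abs(total - total_charge) > 1e-6) {
    stop("total charge constraint violated (", signif(total, 8), ")")
  }
  structure(list(charges = stats::setNames(q, atoms$name), rrms = rrms,
                 total = total), class = "charge_set")
}

# ---- torsion fitting ----------------------------------------------------

#' Torsion energy profile
#'
#' @param atoms Character quadruple naming the scanned dihedral.
#' @param phi Grid of dihedral values, degrees.
#' @param qm Reference energies on the grid, kJ mol-1.
#' @param baseline Energies of the force field with the fitted series
#'   zeroed, kJ mol-1 (default 0).
#' @param conformer Label.
#' @return A `torsion_profile`; both energy curves are shifted so their
#'   minimum is 0.
#' @export
torsion_profile <- function(atoms, phi, qm, baseline = 0, conformer = "") {
  stopifnot(length(atoms) == 4, length(phi) == length(qm))
  baseline <- rep_len(baseline, length(phi))
  structure(list(atoms = as.character(atoms), phi = as.numeric(phi),
                 qm = qm - min(qm), baseline = baseline - min(baseline),
                 conformer = conformer), class = "torsion_profile")
}

#' Fit a cosine torsion series to energy profiles
#'
#' Least-squares fit of V(phi) = sum_n k_n (1 + cos(n phi - phi_s)) to the
#' residual (reference minus baseline) across all supplied conformer
#' profiles simultaneously. Phases are restricted to {0, 180}: negative
#' cosine amplitudes are absorbed as 180-degree phases, so the fit is linear
#' (one free intercept absorbs the arbitrary energy zero).
#'
#' @param profiles A `torsion_profile` or list of them (same dihedral).
#' @param multiplicities Integer set of multiplicities n to include.
#' @return A [torsion_series()] with an attached `residual_rms` attribute
#'   (kJ mol-1) and `intercept`.
#' @export
fit_torsion_series <- function(profiles, multiplicities = 1:4) {
  if (inherits(profiles, "torsion_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile")
  multiplicities <- sort(unique(as.integer(multiplicities)))
  if (!length(multiplicities)) stop("multiplicities must be non-empty")
  phi <- unlist(lapply(profiles, `[[`, "phi"))
  y <- unlist(lapply(profiles, function(p) p$qm - p$baseline))
  if (length(phi) < length(multiplicities) + 1) {
    stop("fewer grid points (", length(phi), ") than free parameters (",
         length(multiplicities) + 1, ")")
  }
  X <- cbind(1, vapply(multiplicities,
                       function(n) cos(.deg2rad(n * phi)), numeric(length(phi))))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients[-1]
  cf[is.na(cf)] <- 0
  terms <- data.frame(k_phi = abs(cf), n = multiplicities,
                      phi_s = ifelse(cf >= 0, 0, 180))
  out <- torsion_series(profiles[[1]]$atoms, terms)
  attr(out, "residual_rms") <- sqrt(mean(fit$residuals^2))
  attr(out, "intercept") <- unname(fit$coefficients[1])
  out
}

# ---- closed-form evaluation --------------------------------------------

#' Evaluate a harmonic bond energy
#' @param term A [bond_term()].
#' @param r Bond length, nm.
#' @return Energy, kJ mol-1: 1/2 kb (r - req)^2.
#' @export
eval_bond <- function(term, r) 0.5 * term$kb * (r - term$req)^2

#' Evaluate a harmonic angle energy
#' @param term An [angle_term()].
#' @param theta Angle, degrees.
#' @return Energy, kJ mol-1: 1/2 k (theta - theta_eq)^2 with the deviation
#'   in radians.
#' @export
eval_angle <- function(term, theta) {
  0.5 * term$k_theta * (.deg2rad(theta - term$theta_eq))^2
}

#' Evaluate a cosine torsion series
#' @param series A [torsion_series()].
#' @param phi Dihedral, degrees (vectorized).
#' @return Energy, kJ mol-1: sum k_phi (1 + cos(n phi - phi_s)).
#' @export
eval_torsion <- function(series, phi) {
  vapply(phi, function(p) {
    sum(series$terms$k_phi *
          (1 + cos(.deg2rad(series$terms$n * p - series$terms$phi_s))))
  }, 0)
}

# ---- bundled SNC parameter set -----------------------------------------

.read_extdata_csv <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "ptmforge"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' The packaged S-nitroso-L-cysteine parameter set
#'
#' Returns the complete published force-field parameter set for the SNC
#' residue: partial charges of the atoms not involved in the amide bond,
#' harmonic bond terms for C-S, S-N and N-O, harmonic angle terms for
#' H-C-S, C-C-S, C-S-N and S-N-O, and the cosine torsion series for
#' C-C-S-N, H-C-S-N and C-S-N-O.
#'
#' @return A `parameter_set`: list with `residue`, `charges` (named numeric,
#'   e), `bonds`, `angles`, `torsions` (lists of term objects) and
#'   `atom_types` (named character map).
#' @export
bundled_snc_parameters <- function() {
  ch <- .read_extdata_csv("snc_charges.csv")
  bo <- .read_extdata_csv("snc_bonds.csv")
  an <- .read_extdata_csv("snc_angles.csv")
  to <- .read_extdata_csv("snc_torsions.csv")
  ty <- .read_extdata_csv("snc_atomtypes.csv")
  bonds <- lapply(seq_len(nrow(bo)), function(r) {
    bond_term(c(bo$a1[r], bo$a2[r]), bo$req[r], bo$kb[r])
  })
  angles <- lapply(seq_len(nrow(an)), function(r) {
    angle_term(c(an$a1[r], an$a2[r], an$a3[r]), an$theta_eq[r], an$k_theta[r],
               corrected = an$a2[r] == "CB")   # CB-centred angles share a center
  })
  keys <- unique(paste(to$a1, to$a2, to$a3, to$a4))
  torsions <- lapply(keys, function(k) {
    rows <- to[paste(to$a1, to$a2, to$a3, to$a4) == k, , drop = FALSE]
    torsion_series(as.character(rows[1, c("a1", "a2", "a3", "a4")]),
                   rows[, c("k_phi", "n", "phi_s")])
  })
  structure(list(residue = "SNC",
                 charges = stats::setNames(ch$charge, ch$atom),
                 bonds = bonds, angles = angles, torsions = torsions,
                 atom_types = stats::setNames(ty$type, ty$atom)),
            class = "parameter_set")
}

#' Construct a parameter set
#' @param residue Residue code.
#' @param charges Named numeric vector, e.
#' @param bonds,angles,torsions Lists of [bond_term()], [angle_term()],
#'   [torsion_series()].
#' @param atom_types Named character map atom name -> force-field type.
#' @return A `parameter_set`.
#' @export
parameter_set <- function(residue, charges, bonds = list(), angles = list(),
                          torsions = list(), atom_types = character(0)) {
  structure(list(residue = residue, charges = charges, bonds = bonds,
                 angles = angles, torsions = torsions,
                 atom_types = atom_types), class = "parameter_set")
}

#' Write GROMACS-dialect include files for a parameter set
#'
#' Emits a residue-topology include (atoms with types and charges) and a
#' bonded-parameter include (bondtypes/angletypes/dihedraltypes sections in
#' GROMACS units: nm, kJ mol-1, degrees). Sections with no terms are
#' omitted. [read_parameter_files()] reproduces the set exactly.
#'
#' @param set A `parameter_set`.
#' @param destination Directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
write_parameter_files <- function(set, destination) {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) formatC(x, format = "g", digits = 10)
  ty <- function(a) {
    t <- set$atom_types[a]
    if (any(is.na(t))) stop("unmapped atom type for: ",
                            paste(a[is.na(t)], collapse = ", "))
    unname(t)
  }
  res_path <- file.path(destination, paste0(tolower(set$residue), "_residue.itp"))
  l <- c(sprintf("; residue topology include for %s", set$residue),
         sprintf("[ %s ]", set$residue), "", " [ atoms ]")
  for (a in names(set$charges)) {
    l <- c(l, sprintf("  %-6s %-6s %12s", a, ty(a), num(set$charges[[a]])))
  }
  writeLines(l, res_path)

  bond_path <- file.path(destination, paste0(tolower(set$residue), "_ffbonded.itp"))
  l <- c(sprintf("; bonded parameters for %s (nm, kJ mol-1, deg)", set$residue))
  if (length(set$bonds)) {
    l <- c(l, "", "[ bondtypes ]")
    for (b in set$bonds) {
      l <- c(l, sprintf("  %-6s %-6s 1 %12s %14s",
                        b$atoms[1], b$atoms[2], num(b$req), num(b$kb)))
    }
  }
  if (length(set$angles)) {
    l <- c(l, "", "[ angletypes ]")
    for (a in set$angles) {
      l <- c(l, sprintf("  %-6s %-6s %-6s 1 %10s %12s",
                        a$atoms[1], a$atoms[2], a$atoms[3],
                        num(a$theta_eq), num(a$k_theta)))
    }
  }
  has_tors <- length(set$torsions) && any(vapply(set$torsions, function(t) nrow(t$terms) > 0, TRUE))
  if (has_tors) {
    l <- c(l, "", "[ dihedraltypes ]")
    for (t in set$torsions) {
      for (r in seq_len(nrow(t$terms))) {
        l <- c(l, sprintf("  %-6s %-6s %-6s %-6s 9 %8s %12s %2d",
                          t$atoms[1], t$atoms[2], t$atoms[3], t$atoms[4],
                          num(t$terms$phi_s[r]), num(t$terms$k_phi[r]),
                          as.integer(t$terms$n[r])))
      }
    }
  }
  writeLines(l, bond_path)
  invisible(c(res_path, bond_path))
}

#' Read back GROMACS-dialect include files written by [write_parameter_files()]
#'
#' @param destination Directory containing the two include files.
#' @param residue Residue code.
#' @return A `parameter_set`.
#' @export
read_parameter_files <- function(destination, residue) {
  res_path <- file.path(destination, paste0(tolower(residue), "_residue.itp"))
  bond_path <- file.path(destination, paste0(tolower(residue), "_ffbonded.itp"))
  strip <- function(path) {
    l <- readLines(path, warn = FALSE)
    l <- sub(";.*$", "", l)
    trimws(l[nzchar(trimws(l))])
  }
  l <- strip(res_path)
  section <- ""
  charges <- numeric(0); types <- character(0)
  for (ln in l) {
    if (grepl("^\\[", ln)) { section <- gsub("[][ ]", "", ln); next }
    if (section == "atoms") {
      tk <- strsplit(ln, "\\s+")[[1]]
      charges[tk[1]] <- as.numeric(tk[3])
      types[tk[1]] <- tk[2]
    }
  }
  l <- strip(bond_path)
  section <- ""
  bonds <- list(); angles <- list(); tor_rows <- list()
  for (ln in l) {
    if (grepl("^\\[", ln)) { section <- gsub("[][ ]", "", ln); next }
    tk <- strsplit(ln, "\\s+")[[1]]
    if (section == "bondtypes") {
      bonds[[length(bonds) + 1L]] <- bond_term(tk[1:2], as.numeric(tk[4]),
                                               as.numeric(tk[5]))
    } else if (section == "angletypes") {
      angles[[length(angles) + 1L]] <- angle_term(tk[1:3], as.numeric(tk[5]),
                                                  as.numeric(tk[6]))
    } else if (section == "dihedraltypes") {
      tor_rows[[length(tor_rows) + 1L]] <- data.frame(
        a1 = tk[1], a2 = tk[2], a3 = tk[3], a4 = tk[4],
        phi_s = as.numeric(tk[6]), k_phi = as.numeric(tk[7]),
        n = as.integer(tk[8]), stringsAsFactors = FALSE)
    }
  }
  torsions <- list()
  if (length(tor_rows)) {
    tdf <- do.call(rbind, tor_rows)
    for (k in unique(paste(tdf$a1, tdf$a2, tdf$a3, tdf$a4))) {
      rows <- tdf[paste(tdf$a1, tdf$a2, tdf$a3, tdf$a4) == k, , drop = FALSE]
      torsions[[length(torsions) + 1L]] <-
        torsion_series(as.character(rows[1, c("a1", "a2", "a3", "a4")]),
                       rows[, c("k_phi", "n", "phi_s")])
    }
  }
  parameter_set(residue, charges, bonds, angles, torsions, types)
}
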