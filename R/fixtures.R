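# Seeded synthetic-fixture generators: every input the analysis and
# parameterization modules need can be produced in-package, so the whole
# pipeline is testable without external QM/MD engines. Each generator uses
# one private pseudorandom stream seeded explicitly; the global RNG state is
# left untouched, and a fixed seed gives bit-reproducible output.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Build a toy polypeptide
#'
#' Extended-conformation (beta strand by default) polypeptide built from the
#' residue template library; valid for PDB writing and all editing
#' operations.
#'
#' @param n_residues Number of residues (>= 1); ignored when `sequence` is
#'   given.
#' @param sequence Optional character vector of 3-letter codes.
#' @param chain Chain id.
#' @param phi,psi Backbone torsions, degrees (default extended beta strand).
#' @return A `ptm_protein`.
#' @export
make_toy_protein <- function(n_residues = 5, sequence = NULL, chain = "A",
                             phi = -135, psi = 135) {
  if (is.null(sequence)) sequence <- rep("ALA", n_residues)
  if (!length(sequence)) stop("need at least one residue")
  p <- ptm_protein()
  for (code in sequence) {
    p <- append_residue(p, chain, code, phi = phi, psi = psi)
  }
  p
}

#' Analytic Hessian of a harmonic bond/angle force field
#'
#' Builds the second-derivative matrix of
#' V = sum 1/2 kb (r - req)^2 + sum 1/2 ktheta (theta - thetaeq)^2
#' at the supplied geometry, which must be the equilibrium of every term
#' (each r equals its req, each theta its thetaeq). The Hessian is exact at
#' equilibrium (computed by central differences of the analytic gradient
#' with a tight step) and symmetrized; units are kJ mol-1 nm-2 with respect
#' to nm displacements.
#'
#' @param positions Nx3 matrix, Angstrom (rownames used as atom names).
#' @param bonds Data frame with columns `i`, `j`, `kb` (kJ mol-1 nm-2);
#'   equilibrium lengths are taken from the geometry.
#' @param angles Optional data frame with columns `i`, `j`, `k`, `k_theta`
#'   (kJ mol-1 rad-2); equilibrium angles from the geometry.
#' @param conformer Label for the bundle.
#' @return A [hessian_bundle()].
#' @export
make_harmonic_hessian <- function(positions, bonds, angles = NULL,
                                  conformer = "alpha") {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  pos_nm <- positions * ANG2NM
  bonds <- as.data.frame(bonds)
  bonds$req <- vapply(seq_len(nrow(bonds)), function(r) {
    sqrt(sum((pos_nm[bonds$i[r], ] - pos_nm[bonds$j[r], ])^2))
  }, 0)
  if (!is.null(angles)) {
    angles <- as.data.frame(angles)
    angles$theta_eq <- vapply(seq_len(nrow(angles)), function(r) {
      v1 <- pos_nm[angles$i[r], ] - pos_nm[angles$j[r], ]
      v2 <- pos_nm[angles$k[r], ] - pos_nm[angles$j[r], ]
      acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    }, 0)
  }
  energy <- function(xvec) {
    p <- matrix(xvec, n, 3, byrow = TRUE)
    e <- 0
    for (r in seq_len(nrow(bonds))) {
      d <- sqrt(sum((p[bonds$i[r], ] - p[bonds$j[r], ])^2))
      e <- e + 0.5 * bonds$kb[r] * (d - bonds$req[r])^2
    }
    if (!is.null(angles)) {
      for (r in seq_len(nrow(angles))) {
        v1 <- p[angles$i[r], ] - p[angles$j[r], ]
        v2 <- p[angles$k[r], ] - p[angles$j[r], ]
        th <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
        e <- e + 0.5 * angles$k_theta[r] * (th - angles$theta_eq[r])^2
      }
    }
    e
  }
  x0 <- as.numeric(t(pos_nm))
  m <- 3 * n
  h <- 1e-5
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      xpp <- x0; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm <- x0; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp <- x0; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm <- x0; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      H[i, j] <- H[j, i] <-
        (energy(xpp) - energy(xpm) - energy(xmp) + energy(xmm)) / (4 * h^2)
    }
  }
  H <- (H + t(H)) / 2
  hessian_bundle(conformer, positions, H, atom_names = rownames(positions))
}

#' Coulomb ESP of point charges on a random shell grid
#'
#' Oracle generator for RESP fitting: the exact Coulomb potential of the
#' given charges evaluated at seeded random points outside 1.4x the van der
#' Waals surface of the atoms.
#'
#' @param atoms Data frame with `name`, `element`, `x`, `y`, `z` (Angstrom).
#' @param charges Numeric vector of generating charges, e.
#' @param n_points Grid size (>= 10 per atom).
#' @param seed Integer seed.
#' @param conformer Label.
#' @param shell_outer Outer shell radius factor (inner is 1.4).
#' @return An [esp_sample()] (potential in e/Angstrom).
#' @export
make_point_charge_esp <- function(atoms, charges, n_points = 100 * nrow(atoms),
                                  seed = 1, conformer = "alpha",
                                  shell_outer = 2.8) {
  stopifnot(length(charges) == nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rv <- vdw_radius(atoms$element)
  .with_seed(seed, {
    pts <- matrix(0, 0, 3)
    while (nrow(pts) < n_points) {
      m <- 4 * (n_points - nrow(pts))
      u <- matrix(stats::rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      anchor <- sample.int(nrow(atoms), m, replace = TRUE)
      rad <- stats::runif(m, 1.4, shell_outer) * rv[anchor]
      cand <- xyz[anchor, , drop = FALSE] + u * rad
      ok <- vapply(seq_len(m), function(p) {
        d <- sqrt(rowSums(sweep(xyz, 2, cand[p, ])^2))
        all(d >= 1.4 * rv - 1e-9)
      }, TRUE)
      pts <- rbind(pts, cand[ok, , drop = FALSE])
    }
    pts <- pts[seq_len(n_points), , drop = FALSE]
    esp <- vapply(seq_len(n_points), function(p) {
      d <- sqrt(rowSums(sweep(xyz, 2, pts[p, ])^2))
      sum(charges / d)
    }, 0)
    esp_sample(conformer, atoms, pts, esp)
  })
}

#' Exact torsion profile of a cosine series
#'
#' @param series A [torsion_series()].
#' @param grid Dihedral grid, degrees (>= 12 points).
#' @param conformer Label.
#' @return A [torsion_profile()] with zero baseline.
#' @export
make_torsion_profile <- function(series, grid = seq(-180, 165, by = 15),
                                 conformer = "alpha") {
  if (length(grid) < 12) stop("torsion grid needs at least 12 points")
  torsion_profile(series$atoms, grid, eval_torsion(series, grid),
                  baseline = 0, conformer = conformer)
}

#' Isotropic Gaussian jitter trajectory
#'
#' Each frame is the reference structure plus independent N(0, sigma^2)
#' noise on every coordinate.
#'
#' @param protein Reference `ptm_protein`.
#' @param sigma Per-coordinate standard deviation, Angstrom.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A [ptm_trajectory()].
#' @export
make_jitter_trajectory <- function(protein, sigma, n_frames, seed = 1) {
  at <- protein_atoms(protein)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  .with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz + matrix(stats::rnorm(length(xyz), 0, sigma), nrow(xyz), 3)
    })
    ptm_trajectory(frames)
  })
}

#' Crooks-consistent Gaussian work samples
#'
#' Forward work ~ N(dG + s2/2, s2) and backward work ~ N(-dG + s2/2, s2)
#' satisfy the Crooks fluctuation relation with free-energy difference dG,
#' so Bennett's estimator applied to the output has analytic truth dG.
#'
#' @param delta_g True free-energy difference, kT.
#' @param sigma2 Work variance, kT^2.
#' @param n Samples per direction.
#' @param seed Integer seed.
#' @return A [work_samples()].
#' @export
make_gaussian_work <- function(delta_g, sigma2 = 1, n = 1e4, seed = 1) {
  .with_seed(seed, {
    fw <- stats::rnorm(n, delta_g + sigma2 / 2, sqrt(sigma2))
    bw <- stats::rnorm(n, -delta_g + sigma2 / 2, sqrt(sigma2))
    work_samples(fw, bw)
  })
}
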