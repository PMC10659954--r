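# Internal-coordinate geometry: NERF building, dihedral measurement,
# quaternion superposition, bond perception and clash counting.
# All coordinates at this layer are in Angstrom.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Internal coordinate triple
#'
#' A bond length, bond angle and torsion describing the position of an atom
#' relative to three reference atoms, as consumed by [nerf_place()].
#'
#' @param r Bond length in Angstrom; must be positive.
#' @param theta Bond angle in degrees, strictly inside (0, 180).
#' @param phi Torsion angle in degrees; normalized to (-180, 180].
#' @return An object of class `internal_coord`.
#' @export
internal_coord <- function(r, theta, phi) {
  stopifnot(is.finite(r), is.finite(theta), is.finite(phi))
  if (r <= 0) stop("bond length r must be positive")
  if (theta <= 0 || theta >= 180) stop("bond angle theta must lie strictly inside (0, 180) degrees")
  structure(list(r = r, theta = theta, phi = .norm_angle(phi)), class = "internal_coord")
}

# normalize an angle in degrees to (-180, 180]
.norm_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y <= -180 + 1e-12] <- 180
  y
}

#' Place an atom from internal coordinates (NERF)
#'
#' Natural Extension of Reference Frame: given three reference positions
#' `a`, `b`, `c` and an internal coordinate (r, theta, phi), returns the
#' position `d` such that |d - c| = r, angle(b, c, d) = theta and the signed
#' dihedral a-b-c-d equals phi (IUPAC convention, cis = 0, right-handed
#' positive).
#'
#' The local frame is built from the b->c direction as first axis and the
#' normal of the (a, b, c) plane as third axis, so results are bit
#' reproducible for identical inputs.
#'
#' @param a,b,c Numeric 3-vectors, Angstrom.
#' @param ic An [internal_coord()] or a list with fields `r`, `theta`, `phi`.
#' @return Numeric 3-vector: the placed position.
#' @export
nerf_place <- function(a, b, c, ic) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  stopifnot(length(a) == 3, length(b) == 3, length(c) == 3)
  ab <- b - a
  bc <- c - b
  cr <- .cross3(ab, bc)
  # triple-product style guard for a degenerate (collinear) reference frame
  if (sqrt(sum(cr^2)) < 1e-8 * max(sqrt(sum(ab^2)) * sqrt(sum(bc^2)), 1e-12)) {
    stop("degenerate reference frame: a, b, c are (near-)collinear")
  }
  u_bc <- .unit(bc)
  n <- .unit(cr)
  m <- .cross3(n, u_bc)
  th <- .deg2rad(ic$theta)
  ph <- .deg2rad(ic$phi)
  d2 <- ic$r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * u_bc + d2[2] * m + d2[3] * n
}

#' Measure internal coordinates of four positions
#'
#' Inverse of [nerf_place()]: returns the bond length |d - c|, the bond angle
#' b-c-d and the signed dihedral a-b-c-d (IUPAC, cis = 0; reported in the
#' range (-180, 180] so the planar trans case reads +180).
#'
#' @param a,b,c,d Numeric 3-vectors, Angstrom.
#' @return An [internal_coord()].
#' @export
measure_internal <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  for (pr in list(list(a, b), list(b, c), list(c, d))) {
    if (sqrt(sum((pr[[1]] - pr[[2]])^2)) < 1e-10) stop("coincident consecutive points")
  }
  r <- sqrt(sum((d - c)^2))
  v1 <- b - c
  v2 <- d - c
  theta <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))))
  internal_coord(r = r, theta = theta, phi = dihedral_angle(a, b, c, d))
}

#' Signed dihedral angle of four positions
#'
#' IUPAC sign convention (cis = 0, right-handed positive), degrees in
#' (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Dihedral in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- as.numeric(b) - as.numeric(a)
  b2 <- as.numeric(c) - as.numeric(b)
  b3 <- as.numeric(d) - as.numeric(c)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * .unit(b2))
  .norm_angle(.rad2deg(atan2(y, x)))
}

#' Optimal rigid superposition (quaternion method)
#'
#' Least-squares superposition of `moving` onto `reference` using Horn's
#' quaternion method (the rotation comes from the principal eigenvector of
#' the 4x4 quaternion cross-covariance matrix, so it is always a proper
#' rotation).
#'
#' @param moving,reference Nx3 numeric matrices with row-wise correspondence,
#'   N >= 3.
#' @return A list with `rotation` (3x3, det +1), `translation` (3-vector) and
#'   `rmsd` (Angstrom). The fitted coordinates are
#'   `moving %*% t(rotation) + translation` (rows).
#' @export
superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference)) stop("point counts differ")
  if (nrow(moving) < 3) stop("need at least 3 points to superpose")
  mc <- colMeans(moving); rc <- colMeans(reference)
  X <- sweep(moving, 2, mc)
  Y <- sweep(reference, 2, rc)
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), nrow = 3, byrow = TRUE)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- rc - as.numeric(R %*% mc)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform to row-wise coordinates
#'
#' @param xyz Nx3 matrix.
#' @param transform List with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return Nx3 matrix of transformed coordinates.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Rotate part of a residue about a named bond axis
#'
#' Rotates `moving_set` atoms by `angle` degrees about the axis defined by two
#' named atoms (right-handed, looking from the first axis atom towards the
#' second). All other atoms are untouched.
#'
#' @param residue A `ptm_residue`.
#' @param axis_atoms Character pair: names of the two axis atoms.
#' @param angle Rotation in degrees.
#' @param moving_set Character vector of atom names to rotate; must exclude
#'   the axis atoms.
#' @return The residue with rotated coordinates.
#' @export
rotate_dihedral <- function(residue, axis_atoms, angle, moving_set) {
  stopifnot(length(axis_atoms) == 2)
  at <- residue$atoms
  i1 <- match(axis_atoms[1], at$name)
  i2 <- match(axis_atoms[2], at$name)
  if (is.na(i1) || is.na(i2)) {
    stop("axis atom(s) not found: ",
         paste(axis_atoms[is.na(c(i1, i2))], collapse = ", "))
  }
  if (any(axis_atoms %in% moving_set)) stop("moving_set must exclude the axis atoms")
  mov <- match(moving_set, at$name)
  if (anyNA(mov)) stop("moving atom(s) not found: ", paste(moving_set[is.na(mov)], collapse = ", "))
  p1 <- as.numeric(at[i1, c("x", "y", "z")])
  p2 <- as.numeric(at[i2, c("x", "y", "z")])
  axis <- .unit(p2 - p1)
  th <- .deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * (K %*% K)
  xyz <- as.matrix(at[mov, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, p1) %*% t(R), 2, p1, `+`)
  at[mov, c("x", "y", "z")] <- xyz
  residue$atoms <- at
  residue
}

# ---- element radius tables ---------------------------------------------

.radius_env <- new.env(parent = emptyenv())

.load_radius_table <- function(which) {
  key <- paste0("tbl_", which)
  if (!is.null(.radius_env[[key]])) return(.radius_env[[key]])
  path <- system.file("extdata", paste0(which, "_radii.csv"), package = "ptmforge")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  v <- stats::setNames(tbl$radius, toupper(tbl$element))
  .radius_env[[key]] <- v
  v
}

#' Covalent radius of an element (Angstrom)
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii.
#' @export
covalent_radius <- function(element) {
  tbl <- .load_radius_table("covalent")
  r <- tbl[toupper(element)]
  if (anyNA(r)) stop("unknown element(s): ", paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' van der Waals radius of an element (Angstrom)
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(element) {
  tbl <- .load_radius_table("vdw")
  r <- tbl[toupper(element)]
  if (anyNA(r)) stop("unknown element(s): ", paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Perceive chemical bonds from interatomic distances
#'
#' Two atoms are considered bonded when their distance is smaller than 120%
#' of the sum of their covalent radii.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param scale Distance criterion as a fraction of the covalent-radius sum;
#'   default 1.2.
#' @return Data frame with integer columns `i`, `j` (i < j), one row per bond.
#' @export
detect_bonds <- function(atoms, scale = 1.2) {
  n <- nrow(atoms)
  rc <- covalent_radius(atoms$element)
  out_i <- integer(0); out_j <- integer(0)
  if (n >= 2) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (i in seq_len(n - 1)) {
      dj <- (i + 1):n
      d <- sqrt(rowSums(sweep(xyz[dj, , drop = FALSE], 2, xyz[i, ])^2))
      hit <- dj[d < scale * (rc[i] + rc[dj])]
      out_i <- c(out_i, rep.int(i, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  data.frame(i = out_i, j = out_j)
}

#' Count steric clashes between candidate atoms and a protein
#'
#' A clash is a heavy-atom pair (one candidate atom, one protein atom) closer
#' than the sum of the van der Waals radii minus `overlap` (default 0.6
#' Angstrom). Atoms of residues listed in `exclude_sites` (typically the
#' residue being edited, whose internal bonded graph must not count) are
#' skipped, as are explicitly excluded pairs.
#'
#' @param protein A `ptm_protein`.
#' @param candidate_atoms Data frame with columns `name`, `element`, `x`,
#'   `y`, `z`.
#' @param exclude_sites List of `c(chain, resnum)` pairs whose protein atoms
#'   are skipped entirely.
#' @param exclusions Optional data frame of excluded pairs with columns
#'   `cand_name`, `chain`, `resnum`, `atom_name`.
#' @param overlap Allowed vdW overlap in Angstrom before a pair counts as a
#'   clash (single tunable constant of the criterion).
#' @return Integer clash count.
#' @export
count_clashes <- function(protein, candidate_atoms, exclude_sites = list(),
                          exclusions = NULL, overlap = 0.6) {
  if (is.null(candidate_atoms) || nrow(candidate_atoms) == 0) return(0L)
  pa <- protein_atoms(protein)
  if (nrow(pa) == 0) return(0L)
  pa <- pa[toupper(pa$element) != "H", , drop = FALSE]
  ca <- candidate_atoms[toupper(candidate_atoms$element) != "H", , drop = FALSE]
  if (nrow(pa) == 0 || nrow(ca) == 0) return(0L)
  if (length(exclude_sites)) {
    keys <- vapply(exclude_sites, function(s) paste(s[1], s[2], sep = ":"), "")
    pa <- pa[!(paste(pa$chain, pa$resnum, sep = ":") %in% keys), , drop = FALSE]
    if (nrow(pa) == 0) return(0L)
  }
  rp <- vdw_radius(pa$element)
  rcand <- vdw_radius(ca$element)
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  n <- 0L
  for (k in seq_len(nrow(ca))) {
    d <- sqrt(rowSums(sweep(pxyz, 2, as.numeric(ca[k, c("x", "y", "z")]))^2))
    hit <- d < (rp + rcand[k] - overlap)
    if (!is.null(exclusions) && any(hit)) {
      ex <- exclusions[exclusions$cand_name == ca$name[k], , drop = FALSE]
      if (nrow(ex)) {
        exkey <- paste(ex$chain, ex$resnum, ex$atom_name, sep = ":")
        hit <- hit & !(paste(pa$chain, pa$resnum, pa$name, sep = ":") %in% exkey)
      }
    }
    n <- n + sum(hit)
  }
  as.integer(n)
}
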