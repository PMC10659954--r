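# Post-simulation statistics: persistent close contacts, RMSF, and free
# energies from forward/backward work samples via Bennett's acceptance
# ratio. Work/energy values are in kT internally; conversion helpers are
# provided for kJ mol-1.

.KB_KJ_PER_MOL_K <- 0.00831446261815324

#' Convert energies between kT and kJ/mol
#' @param x Numeric values.
#' @param temperature Kelvin.
#' @return Converted values.
#' @export
kt_to_kj_per_mol <- function(x, temperature = 300) x * .KB_KJ_PER_MOL_K * temperature

#' @rdname kt_to_kj_per_mol
#' @export
kj_per_mol_to_kt <- function(x, temperature = 300) x / (.KB_KJ_PER_MOL_K * temperature)

#' Trajectory container
#'
#' @param coords Either a 3-dimensional array (frames x atoms x 3) or a list
#'   of Nx3 frame matrices with identical atom count and ordering, Angstrom.
#' @param frame_interval Opaque time spacing between frames.
#' @return A `ptm_trajectory` holding a frames x atoms x 3 array.
#' @export
ptm_trajectory <- function(coords, frame_interval = 1) {
  if (is.list(coords)) {
    n <- unique(vapply(coords, nrow, 0L))
    if (length(n) != 1) stop("all frames must have the same atom count")
    arr <- array(0, c(length(coords), n, 3))
    for (f in seq_along(coords)) arr[f, , ] <- as.matrix(coords[[f]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  structure(list(coords = coords, frame_interval = frame_interval),
            class = "ptm_trajectory")
}

#' Read a trajectory from a whitespace-delimited coordinate table
#'
#' Text schema: one row per atom per frame with columns
#' `frame atom x y z` (header optional, `#` comments ignored); atoms must
#' appear in the same order in every frame.
#'
#' @param path File path.
#' @return A `ptm_trajectory`.
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  names(df)[1:5] <- c("frame", "atom", "x", "y", "z")
  frames <- split(df, df$frame)
  ptm_trajectory(lapply(frames, function(f) as.matrix(f[, c("x", "y", "z")])))
}

#' Persistent close contacts around a site
#'
#' A residue qualifies as a close contact of the site residue when any of
#' its atoms lies within `cutoff_nm` (default 0.35 nm) of any site-residue
#' atom in at least `persistence` (default 70%) of the frames. Residues
#' forming peptide bonds with the site residue (sequence neighbours i-1 and
#' i+1 of the same chain) are excluded. The trajectory atom roster must
#' match the flattened protein atom table row-for-row.
#'
#' @param traj A `ptm_trajectory`.
#' @param protein The `ptm_protein` defining the atom roster.
#' @param site Site string or selector.
#' @param cutoff_nm Contact distance threshold, nm.
#' @param persistence Minimum fraction of frames (all supplied frames count;
#'   any equilibration trimming is the caller's concern).
#' @return A `contact_report`: list with `contacts` (data frame chain,
#'   resnum, resname, persistence) and `count`.
#' @export
close_contacts <- function(traj, protein, site, cutoff_nm = 0.35,
                           persistence = 0.7) {
  if (is.character(site)) site <- parse_site(site)
  at <- protein_atoms(protein)
  if (dim(traj$coords)[2] != nrow(at)) {
    stop("trajectory atom roster (", dim(traj$coords)[2],
         ") does not map onto the protein atom table (", nrow(at), ")")
  }
  find_residue(protein, site)   # validates the site
  cutoff <- cutoff_nm * 10      # structure layer is Angstrom
  site_idx <- which(at$chain == site$chain & at$resnum == site$resnum)
  reskey <- paste(at$chain, at$resnum)
  other_keys <- setdiff(unique(reskey), unique(reskey[site_idx]))
  # exclude peptide-bonded neighbours
  excl <- paste(site$chain, c(site$resnum - 1L, site$resnum + 1L))
  other_keys <- setdiff(other_keys, excl)
  nf <- dim(traj$coords)[1]
  hits <- stats::setNames(integer(length(other_keys)), other_keys)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    sxyz <- xyz[site_idx, , drop = FALSE]
    for (k in other_keys) {
      oxyz <- xyz[reskey == k, , drop = FALSE]
      dmin <- min(vapply(seq_len(nrow(sxyz)), function(a) {
        min(sqrt(rowSums(sweep(oxyz, 2, sxyz[a, ])^2)))
      }, 0))
      if (dmin < cutoff) hits[k] <- hits[k] + 1L
    }
  }
  frac <- hits / nf
  sel <- frac >= persistence
  keys <- names(frac)[sel]
  parts <- strsplit(keys, " ", fixed = TRUE)
  contacts <- data.frame(
    chain = vapply(parts, `[[`, "", 1),
    resnum = as.integer(vapply(parts, `[[`, "", 2)),
    persistence = unname(frac[sel]))
  contacts$resname <- vapply(seq_len(nrow(contacts)), function(r) {
    at$resname[match(paste(contacts$chain[r], contacts$resnum[r]), reskey)]
  }, "")
  contacts <- contacts[order(contacts$chain, contacts$resnum), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(site = site, contacts = contacts, count = nrow(contacts)),
            class = "contact_report")
}

#' Root-mean-square fluctuations per atom
#'
#' Each frame is optimally superposed onto the mean structure (the fit is
#' iterated once: fit to the running mean, recompute the mean, refit), after
#' which RMSF_a = sqrt(mean |x_a - <x_a>|^2).
#'
#' @param traj A `ptm_trajectory` with >= 2 frames.
#' @param selection Optional integer atom indices to fit and report (default
#'   all atoms).
#' @return Numeric vector of per-atom fluctuations, Angstrom.
#' @export
rmsf <- function(traj, selection = NULL) {
  nf <- dim(traj$coords)[1]
  if (nf < 2) stop("RMSF requires at least two frames")
  na <- dim(traj$coords)[2]
  if (is.null(selection)) selection <- seq_len(na)
  frames <- lapply(seq_len(nf), function(f) traj$coords[f, selection, , drop = TRUE])
  mean_xyz <- Reduce(`+`, frames) / nf
  for (pass in 1:2) {
    frames <- lapply(frames, function(x) apply_transform(x, superpose(x, mean_xyz)))
    mean_xyz <- Reduce(`+`, frames) / nf
  }
  dev2 <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mean_xyz)^2))) / nf
  sqrt(dev2)
}

#' Forward/backward alchemical work samples
#'
#' @param forward Work values for the 0 -> 1 switch, kT.
#' @param backward Work values for the 1 -> 0 switch, kT.
#' @param temperature Kelvin (bookkeeping only; values are already in kT).
#' @return A `work_samples` object.
#' @export
work_samples <- function(forward, backward, temperature = 300) {
  if (!length(forward) || !length(backward)) {
    stop("both forward and backward samples must be non-empty")
  }
  if (!all(is.finite(forward)) || !all(is.finite(backward))) {
    stop("work values must be finite")
  }
  structure(list(forward = as.numeric(forward), backward = as.numeric(backward),
                 temperature = temperature), class = "work_samples")
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Solves the Bennett self-consistency equation
#' sum_F f(M + W_F - dG) = sum_R f(-M + W_R + dG), with f the Fermi function
#' and M = log(nF/nR), by bracketed root finding to 1e-10. The uncertainty
#' is the standard asymptotic variance estimate; when the forward and
#' backward work distributions barely overlap the variance estimate
#' diverges and the result is flagged.
#'
#' @param samples A [work_samples()].
#' @return A `bar_result`: list with `delta_g` (kT), `se` (kT) and
#'   `overlap_warning` (logical).
#' @export
bar_delta_g <- function(samples) {
  wf <- samples$forward; wr <- samples$backward
  nf <- length(wf); nr <- length(wr)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(dg) sum(fermi(M + wf - dg)) - sum(fermi(-M + wr + dg))
  # g is increasing in dg: g(-Inf) = -nr, g(+Inf) = +nf
  lo <- min(-wr) - 10; hi <- max(wf) + 10
  while (g(lo) > 0) lo <- lo - 10
  while (g(hi) < 0) hi <- hi + 10
  dg <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  ff <- fermi(M + wf - dg)
  fr <- fermi(-M + wr + dg)
  varf <- (mean(ff^2) / mean(ff)^2 - 1) / nf
  varr <- (mean(fr^2) / mean(fr)^2 - 1) / nr
  v <- varf + varr
  warn <- !is.finite(v) || mean(ff) < 1e-12 || mean(fr) < 1e-12
  structure(list(delta_g = dg, se = sqrt(max(v, 0)), overlap_warning = warn),
            class = "bar_result")
}

#' Chain per-leg free energies into a total
#'
#' @param per_leg Ordered numeric vector of per-leg free-energy differences
#'   (kT), in the order of the schedule's flattened leg list.
#' @param schedule Optional `ti_schedule`; when supplied the leg count must
#'   match and stage subtotals are reported.
#' @return List with `total` and, with a schedule, `stage_totals`.
#' @export
chain_delta_g <- function(per_leg, schedule = NULL) {
  out <- list(total = sum(per_leg))
  if (!is.null(schedule)) {
    if (length(per_leg) != nrow(schedule$legs)) {
      stop("leg count (", length(per_leg), ") does not match the schedule (",
           nrow(schedule$legs), ")")
    }
    out$stage_totals <- tapply(per_leg, schedule$legs$stage, sum)
  }
  out
}
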