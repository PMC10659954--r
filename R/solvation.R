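# SLTCAP ion-count planning with protein-volume exclusion.

.NA_PER_NM3_PER_M <- 0.602214076   # ions per nm^3 at 1 mol/L

#' SLTCAP ion counts for a charged solute
#'
#' Screening Layer Tally by Container Average Potential: the number of
#' monovalent cations and anions that reproduce a bulk salt concentration
#' around a solute of net charge Q, counting only the water volume (the
#' protein volume is excluded to mimic dilute conditions). The continuous
#' solution is N+- = N0 (sqrt(1 + t^2) -+ t) with N0 = c0 NA V and
#' t = Q / (2 N0), which satisfies N+ - N- = -Q and N+ N- = N0^2; counts are
#' rounded half-up, preserving exact neutrality for integer Q.
#'
#' @param Q Net solute charge, elementary charges.
#' @param c0 Bulk monovalent salt concentration, mol/L (>= 0).
#' @param V_water Water volume, nm^3 (> 0).
#' @return An `ion_plan`: list with integer `n_cations`, `n_anions`, the
#'   continuous `N_plus`, `N_minus`, and `N0`.
#' @export
sltcap_ion_counts <- function(Q, c0, V_water) {
  if (c0 < 0) stop("salt concentration must be non-negative")
  if (V_water <= 0) stop("water volume must be positive")
  N0 <- c0 * .NA_PER_NM3_PER_M * V_water
  if (N0 == 0) {
    # pure neutralization limit
    n_cat <- max(0, round(-Q)); n_an <- max(0, round(Q))
    Np <- max(0, -Q); Nm <- max(0, Q)
  } else {
    t <- Q / (2 * N0)
    Np <- N0 * (sqrt(1 + t^2) - t)
    Nm <- N0 * (sqrt(1 + t^2) + t)
    n_cat <- floor(Np + 0.5)
    n_an <- floor(Nm + 0.5)
  }
  if (abs((n_cat - n_an) + round(Q)) > .Machine$double.eps * 4) {
    stop("ion neutrality violated after rounding (non-integer charge ",
         Q, "?); supply an integer net charge")
  }
  structure(list(protein_charge = Q, bulk_concentration = c0,
                 water_volume = V_water,
                 n_cations = as.integer(n_cat), n_anions = as.integer(n_an),
                 N_plus = Np, N_minus = Nm, N0 = N0),
            class = "ion_plan")
}

.volume_env <- new.env(parent = emptyenv())

.residue_volume_table <- function() {
  if (is.null(.volume_env$tbl)) {
    tbl <- utils::read.csv(system.file("extdata", "residue_volumes_synthetic.csv",
                                       package = "ptmforge"),
                           comment.char = "#", stringsAsFactors = FALSE)
    .volume_env$tbl <- stats::setNames(tbl$volume_nm3, toupper(tbl$residue))
  }
  .volume_env$tbl
}

#' Protein volume from per-residue volumes
#'
#' Sums bundled mean residue volumes (from tessellation-style volumetric
#' statistics of folded proteins; see the packaged table for provenance).
#'
#' @param protein A `ptm_protein`.
#' @return Volume in nm^3 (0 for an empty protein).
#' @export
protein_volume <- function(protein) {
  tbl <- .residue_volume_table()
  total <- 0
  for (ch in protein$chains) {
    for (res in ch$residues) {
      v <- tbl[res$name]
      if (is.na(v)) stop("no bundled volume for residue '", res$name, "'")
      total <- total + unname(v)
    }
  }
  total
}

#' Simulation box volume
#'
#' @param d Characteristic box length, nm: for `"cubic"` the edge; for
#'   `"dodecahedron"` (rhombic dodecahedron) the image distance (box vector
#'   length), giving V = sqrt(2)/2 d^3.
#' @param type Box type.
#' @return Volume, nm^3.
#' @export
box_volume <- function(d, type = c("dodecahedron", "cubic")) {
  type <- match.arg(type)
  if (d <= 0) stop("box length must be positive")
  switch(type, cubic = d^3, dodecahedron = sqrt(2) / 2 * d^3)
}
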