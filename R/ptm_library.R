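# PTM registry and structure-editing operations: mutate, modify,
# prepend/append, capped-dipeptide building, and the chi1/chi2 rotamer
# clash scan (30 degree grid, deterministic order).

# Registry of (amino acid, reaction) pairs reachable through modify().
# `in_table` marks the printed registry; hydroxyl acetylation of SER/THR/TYR
# is additionally reachable (documented worked example) but not listed.
.modification_registry <- function() {
  reg <- rbind(
    data.frame(residue = "ARG",
               reaction = c("Methylation", "Symmetric demethylation",
                            "Asymmetric demethylation", "Phosphorylation"),
               product = c("NMM", "2MR", "DA2", "PHR"), in_table = TRUE),
    data.frame(residue = "ASP", reaction = "Phosphorylation",
               product = "PHD", in_table = TRUE),
    data.frame(residue = "CYS",
               reaction = c("Carbamylation (carbamoylation)", "Cyanylation",
                            "Cysteinylation", "Glutathionylation", "Methylation",
                            "Nitrosylation (nitrosation)", "Phosphorylation",
                            "Sulfenylation", "Sulfhydration", "Sulfinylation",
                            "Sulfonylation"),
               product = c("QCS", "XCN", "IYY", "CGL", "SMC", "SNC", "CSP",
                           "CSO", "CSS", "CSD", "OCS"), in_table = TRUE),
    data.frame(residue = "GLU", reaction = "Methylation", product = "GME",
               in_table = TRUE),
    data.frame(residue = "HIS", reaction = c("Methylation", "Phosphorylation"),
               product = c("HIC", "NEP"), in_table = TRUE),
    data.frame(residue = "LYS",
               reaction = c("Acetylation", "Methylation", "Dimethylation",
                            "Trimethylation", "Phosphorylation"),
               product = c("ALY", "MLZ", "MLY", "M3L", "PLK"), in_table = TRUE),
    data.frame(residue = "SER", reaction = "Phosphorylation", product = "SEP",
               in_table = TRUE),
    data.frame(residue = "THR", reaction = "Phosphorylation", product = "TPO",
               in_table = TRUE),
    data.frame(residue = "TYR", reaction = "Phosphorylation", product = "PTR",
               in_table = TRUE),
    data.frame(residue = c("SER", "THR", "TYR"), reaction = "Acetylation",
               product = c("ASE", "ATH", "ATY"), in_table = FALSE)
  )
  reg
}

# canonical lowercase reaction key with alias folding
.reaction_key <- function(reaction) {
  r <- tolower(trimws(reaction))
  r <- sub("\\s*\\(.*\\)$", "", r)      # strip parenthetical alias
  aliases <- c(nitrosation = "nitrosylation",
               carbamoylation = "carbamylation",
               "symmetric dimethylation" = "symmetric demethylation",
               "asymmetric dimethylation" = "asymmetric demethylation")
  ifelse(r %in% names(aliases), unname(aliases[r]), r)
}

#' List the post-translational modifications reachable through [modify()]
#'
#' Returns the printed (amino acid, reaction) registry. N-terminal
#' acetylation is reachable only through [prepend()] and is deliberately not
#' listed.
#'
#' @param residue Optional 3-letter code to filter by amino acid.
#' @return Data frame with columns `amino_acid` and `reaction`.
#' @export
list_modifications <- function(residue = NULL) {
  reg <- .modification_registry()
  reg <- reg[reg$in_table, c("residue", "reaction")]
  names(reg) <- c("amino_acid", "reaction")
  if (!is.null(residue)) reg <- reg[reg$amino_acid == toupper(residue), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

# attachment stems: three existing atoms (a, b, c) from which moiety recipes
# chain, per target residue
.attachment_stem <- function(resname) {
  switch(resname,
    CYS = c("CA", "CB", "SG"),
    SER = c("CA", "CB", "OG"),
    THR = c("CA", "CB", "OG1"),
    TYR = c("CE1", "CZ", "OH"),
    ARG = c("NE", "CZ", "NH1"),
    LYS = c("CD", "CE", "NZ"),
    HIS = c("CG", "CD2", "NE2"),
    ASP = c("CB", "CG", "OD2"),
    GLU = c("CG", "CD", "OE2"),
    stop("no attachment stem defined for residue ", resname))
}

# Moiety recipes: rows (name, element, ref1..3, r, theta, phi). Refs S1-S3
# are the stem atoms; other refs are earlier moiety atoms. Cysteine products
# reuse the tail atom names/geometry of the bundled product templates.
.moiety_recipe <- function(resname, key) {
  S <- function(name, element, r1, r2, r3, r, th, ph) {
    list(name = name, element = element, refs = c(r1, r2, r3),
         r = r, theta = th, phi = ph)
  }
  if (resname == "CYS") {
    return(switch(key,
      nitrosylation = list(S("ND", "N", "S1", "S2", "S3", 1.918, 99.5, 180),
                           S("OE", "O", "S2", "S3", "ND", 1.170, 117.2, 180)),
      sulfhydration = list(S("SD", "S", "S1", "S2", "S3", 2.050, 103.0, 180)),
      methylation = list(S("CS", "C", "S1", "S2", "S3", 1.810, 100.2, 180)),
      cyanylation = list(S("CD", "C", "S1", "S2", "S3", 1.680, 100.0, 180),
                         S("NE", "N", "S2", "S3", "CD", 1.160, 177.0, 180)),
      sulfenylation = list(S("OD", "O", "S1", "S2", "S3", 1.670, 104.0, 180)),
      sulfinylation = list(S("OD1", "O", "S1", "S2", "S3", 1.470, 106.0, 60),
                           S("OD2", "O", "S1", "S2", "S3", 1.470, 106.0, 170)),
      sulfonylation = list(S("OD1", "O", "S1", "S2", "S3", 1.440, 106.0, 60),
                           S("OD2", "O", "S1", "S2", "S3", 1.440, 106.0, 180),
                           S("OD3", "O", "S1", "S2", "S3", 1.440, 106.0, -60)),
      carbamylation = list(S("CD", "C", "S1", "S2", "S3", 1.790, 100.0, 180),
                           S("OD", "O", "S2", "S3", "CD", 1.220, 122.0, 0),
                           S("ND", "N", "S2", "S3", "CD", 1.330, 115.0, 180)),
      phosphorylation = list(S("P", "P", "S1", "S2", "S3", 2.100, 100.0, 180),
                             S("O1P", "O", "S2", "S3", "P", 1.480, 109.5, 60),
                             S("O2P", "O", "S2", "S3", "P", 1.480, 109.5, 180),
                             S("O3P", "O", "S2", "S3", "P", 1.480, 109.5, -60)),
      cysteinylation = list(S("SD", "S", "S1", "S2", "S3", 2.040, 103.0, 180),
                            S("CB2", "C", "S2", "S3", "SD", 1.810, 103.0, 90),
                            S("CA2", "C", "S3", "SD", "CB2", 1.530, 114.0, 180),
                            S("N2", "N", "SD", "CB2", "CA2", 1.460, 110.0, -65),
                            S("C2", "C", "SD", "CB2", "CA2", 1.530, 110.0, 170),
                            S("O2", "O", "CB2", "CA2", "C2", 1.231, 121.0, 0)),
      glutathionylation = list(
        S("SD", "S", "S1", "S2", "S3", 2.050, 103.0, 180),
        S("CB2", "C", "S2", "S3", "SD", 1.810, 103.0, 90),
        S("CA2", "C", "S3", "SD", "CB2", 1.530, 114.0, 180),
        S("N2", "N", "SD", "CB2", "CA2", 1.460, 110.0, -65),
        S("C2", "C", "SD", "CB2", "CA2", 1.530, 110.0, 170),
        S("O2", "O", "CB2", "CA2", "C2", 1.231, 121.0, 0),
        S("N3", "N", "CB2", "CA2", "C2", 1.329, 116.2, 180),
        S("CA3", "C", "CA2", "C2", "N3", 1.451, 121.7, 180),
        S("C3", "C", "C2", "N3", "CA3", 1.516, 110.0, 180),
        S("O31", "O", "N3", "CA3", "C3", 1.249, 118.4, 0),
        S("O32", "O", "N3", "CA3", "C3", 1.249, 118.4, 180),
        S("CD1", "C", "CB2", "CA2", "N2", 1.329, 121.0, 120),
        S("OE1", "O", "CA2", "N2", "CD1", 1.231, 123.0, 0),
        S("CG1", "C", "CA2", "N2", "CD1", 1.516, 115.0, 180),
        S("CB1", "C", "N2", "CD1", "CG1", 1.520, 112.0, 180),
        S("CA1", "C", "CD1", "CG1", "CB1", 1.530, 112.0, 180),
        S("N1", "N", "CG1", "CB1", "CA1", 1.460, 110.0, -65),
        S("C1", "C", "CG1", "CB1", "CA1", 1.530, 110.0, 65),
        S("O11", "O", "CB1", "CA1", "C1", 1.249, 118.4, 0),
        S("O12", "O", "CB1", "CA1", "C1", 1.249, 118.4, 180)),
      stop("no moiety recipe for CYS ", key)))
  }
  # generic attachments for non-cysteine residues
  switch(key,
    phosphorylation = list(S("P", "P", "S1", "S2", "S3", 1.610, 119.0, 180),
                           S("O1P", "O", "S2", "S3", "P", 1.480, 109.5, 60),
                           S("O2P", "O", "S2", "S3", "P", 1.480, 109.5, 180),
                           S("O3P", "O", "S2", "S3", "P", 1.480, 109.5, -60)),
    acetylation = list(S("CX", "C", "S1", "S2", "S3", 1.360, 117.0, 180),
                       S("OX", "O", "S2", "S3", "CX", 1.210, 123.0, 0),
                       S("CMX", "C", "S2", "S3", "CX", 1.500, 112.0, 180)),
    methylation = list(S("CX", "C", "S1", "S2", "S3", 1.460, 112.0, 180)),
    dimethylation = ,
    `symmetric demethylation` = ,
    `asymmetric demethylation` = list(
      S("CX1", "C", "S1", "S2", "S3", 1.460, 112.0, 150),
      S("CX2", "C", "S1", "S2", "S3", 1.460, 112.0, -90)),
    trimethylation = list(S("CX1", "C", "S1", "S2", "S3", 1.490, 109.5, 60),
                          S("CX2", "C", "S1", "S2", "S3", 1.490, 109.5, 180),
                          S("CX3", "C", "S1", "S2", "S3", 1.490, 109.5, -60)),
    stop("no moiety recipe for reaction ", key))
}

# ---- chi scan machinery -------------------------------------------------

# set chi torsions of a residue to absolute values using a template's chi
# definitions; returns the residue
.set_chis <- function(res, tpl, chi1 = NULL, chi2 = NULL) {
  for (which in c("chi1", "chi2")) {
    target <- if (which == "chi1") chi1 else chi2
    chi <- tpl$chi[[which]]
    if (is.null(target) || is.null(chi)) next
    nm <- chi$atoms
    at <- res$atoms
    idx <- match(nm, at$name)
    if (anyNA(idx)) next
    cur <- dihedral_angle(as.numeric(at[idx[1], c("x", "y", "z")]),
                          as.numeric(at[idx[2], c("x", "y", "z")]),
                          as.numeric(at[idx[3], c("x", "y", "z")]),
                          as.numeric(at[idx[4], c("x", "y", "z")]))
    moving <- intersect(.chi_moving_set(tpl, which), at$name)
    moving <- setdiff(moving, nm[2:3])
    res <- rotate_dihedral(res, nm[2:3], target - cur, moving)
  }
  res
}

# scan chi1 (outer) and chi2 (inner) on a 30 degree grid starting from the
# template defaults; first clash-free combination wins, otherwise the
# least-clash conformation is kept and a warning recorded.
.chi_scan <- function(protein, site, res, tpl) {
  sidechain <- function(r) {
    r$atoms[!(r$atoms$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  }
  nclash <- function(r) count_clashes(protein, sidechain(r),
                                      exclude_sites = list(c(site$chain, site$resnum)))
  n0 <- nclash(res)
  if (n0 == 0 || is.null(tpl$chi$chi1)) {
    if (n0 > 0) warning("clashes could not be avoided (no scannable torsion); ",
                        n0, " clash(es) remain")
    return(res)
  }
  chi1_0 <- tpl$chi$chi1$default
  chi2_0 <- if (!is.null(tpl$chi$chi2)) tpl$chi$chi2$default else NA
  grid <- seq(0, 330, by = 30)
  best <- res; best_n <- n0
  for (d1 in grid) {
    for (d2 in (if (is.na(chi2_0)) 0 else grid)) {
      cand <- .set_chis(res, tpl, chi1 = chi1_0 + d1,
                        chi2 = if (is.na(chi2_0)) NULL else chi2_0 + d2)
      n <- nclash(cand)
      if (n == 0) return(cand)
      if (n < best_n) { best <- cand; best_n <- n }
      if (is.na(chi2_0)) break
    }
  }
  warning("clashes could not be avoided; keeping conformation with ",
          best_n, " clash(es)")
  best
}

# ---- editing operations -------------------------------------------------

#' Point-mutate a residue
#'
#' Replaces the residue addressed by `site` with `new_residue`, keeping the
#' backbone atoms (N, CA, C, O) at their original coordinates and rebuilding
#' the side chain from the template library. If the new side chain clashes
#' with pre-existing atoms, chi1/chi2 are scanned in 30 degree increments
#' (chi1 outer loop, chi2 inner, starting from the template values); the
#' first clash-free combination is kept, otherwise the conformation with the
#' least number of clashes (with a warning).
#'
#' @param protein A `ptm_protein`.
#' @param site Site string (e.g. `"A:CYS155"` or `"A:155"`) or
#'   `site_selector`.
#' @param new_residue 3-letter code of the replacement (standard or PTM
#'   residue).
#' @return The modified protein.
#' @export
mutate <- function(protein, site, new_residue) {
  if (is.character(site)) site <- parse_site(site)
  old <- find_residue(protein, site)
  tpl <- residue_template(new_residue)
  at <- old$atoms
  seed <- list()
  for (nm in c("N", "CA", "C")) {
    i <- match(nm, at$name)
    if (is.na(i)) stop("residue ", format_site(site), " lacks backbone atom ", nm)
    seed[[nm]] <- as.numeric(at[i, c("x", "y", "z")])
  }
  newat <- .build_from_template(tpl, seed)
  # keep the original O exactly (backbone untouched)
  io_old <- match("O", at$name); io_new <- match("O", newat$name)
  if (!is.na(io_old) && !is.na(io_new)) {
    newat[io_new, c("x", "y", "z")] <- at[io_old, c("x", "y", "z")]
  }
  res <- ptm_residue(tpl$code, old$number, newat, old$insertion_code)
  res <- .chi_scan(protein, site, res, tpl)
  .set_residue(protein, site, res)
}

#' Apply a chemical modification to a residue
#'
#' Looks up the (residue, reaction) pair in the modification registry,
#' builds the new moiety atoms with NERF from the attachment recipe, renames
#' the residue to the product code, and runs the same chi1/chi2 clash scan
#' as [mutate()]. Leaving atoms are hydrogens and therefore implicit in the
#' heavy-atom model.
#'
#' @param protein A `ptm_protein`.
#' @param site Site string or `site_selector`.
#' @param reaction Reaction name, e.g. `"nitrosylation"` (case-insensitive;
#'   published aliases such as "nitrosation" are accepted).
#' @return The modified protein.
#' @export
modify <- function(protein, site, reaction) {
  if (is.character(site)) site <- parse_site(site)
  res <- find_residue(protein, site)
  reg <- .modification_registry()
  rows <- reg[reg$residue == res$name, , drop = FALSE]
  key <- .reaction_key(reaction)
  hit <- rows[.reaction_key(rows$reaction) == key, , drop = FALSE]
  if (!nrow(hit)) {
    valid <- .reaction_key(rows$reaction[rows$in_table])
    stop("reaction '", reaction, "' is not registered for ", res$name,
         if (length(valid)) paste0("; valid reactions: ", paste(valid, collapse = ", "))
         else "; no reactions are registered for this residue")
  }
  stem_names <- .attachment_stem(res$name)
  at <- res$atoms
  idx <- match(stem_names, at$name)
  if (anyNA(idx)) stop("residue ", format_site(site), " lacks attachment atom(s): ",
                       paste(stem_names[is.na(idx)], collapse = ", "))
  pos <- list(S1 = as.numeric(at[idx[1], c("x", "y", "z")]),
              S2 = as.numeric(at[idx[2], c("x", "y", "z")]),
              S3 = as.numeric(at[idx[3], c("x", "y", "z")]))
  recipe <- .moiety_recipe(res$name, key)
  new_rows <- list()
  for (m in recipe) {
    ref <- lapply(m$refs, function(nm) {
      p <- pos[[nm]]
      if (is.null(p)) stop("moiety recipe references unknown atom ", nm)
      p
    })
    p <- nerf_place(ref[[1]], ref[[2]], ref[[3]],
                    internal_coord(m$r, m$theta, m$phi))
    pos[[m$name]] <- p
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      name = m$name, element = m$element, x = p[1], y = p[2], z = p[3],
      occupancy = 1, altloc = "", hetero = FALSE, stringsAsFactors = FALSE)
  }
  at <- rbind(at, do.call(rbind, new_rows))
  product <- ptm_residue(hit$product[1], res$number, at, res$insertion_code)
  # scan with the product template when one is bundled (cysteine products)
  tpl <- tryCatch(residue_template(hit$product[1]), error = function(e) NULL)
  if (!is.null(tpl)) product <- .chi_scan(protein, site, product, tpl)
  .set_residue(protein, site, product)
}

# shared helper: build a residue appended after (or prepended before) an
# anchor residue's backbone, at the given backbone torsions
.amide <- list(CN = 1.329, angle_CAC_N = 116.6, angle_C_N_CA = 121.7,
               NCA = 1.458, CAC = 1.525, angle_N_CA_C = 111.2, omega = 180)

#' Append a residue at the C-terminus of a chain
#'
#' The new residue is built with NERF at standard trans-amide geometry. When
#' `phi`/`psi` are not given, the extended beta-strand conformation
#' (-135, 135) is used. `psi` is the psi torsion of the previously terminal
#' residue (which the new amide nitrogen defines); `phi` is the phi torsion
#' of the new residue.
#'
#' @param protein A `ptm_protein` (may be empty).
#' @param chain Chain id; created when absent.
#' @param residue 3-letter code (`"NME"` caps the C-terminus).
#' @param phi,psi Backbone torsions in degrees.
#' @return The extended protein.
#' @export
append_residue <- function(protein, chain, residue,
                           phi = .beta_phi, psi = .beta_psi) {
  tpl <- residue_template(residue)
  ci <- which(vapply(protein$chains, `[[`, "", "id") == chain)
  if (!length(ci) || !length(protein$chains[[ci]]$residues)) {
    return(.seed_chain(protein, chain, tpl, psi))
  }
  ch <- protein$chains[[ci]]
  last <- ch$residues[[length(ch$residues)]]
  g <- function(res, nm) {
    i <- match(nm, res$atoms$name)
    if (is.na(i)) stop("anchor residue lacks backbone atom ", nm)
    as.numeric(res$atoms[i, c("x", "y", "z")])
  }
  Np <- g(last, "N"); CAp <- g(last, "CA"); Cp <- g(last, "C")
  N <- nerf_place(Np, CAp, Cp, internal_coord(.amide$CN, .amide$angle_CAC_N, psi))
  # reposition the anchor's carbonyl O trans to the new amide N
  io <- match("O", last$atoms$name)
  if (!is.na(io)) {
    O <- nerf_place(Np, CAp, Cp, internal_coord(1.231, 120.5, psi - 180))
    last$atoms[io, c("x", "y", "z")] <- O
    ch$residues[[length(ch$residues)]] <- last
  }
  CA2 <- nerf_place(CAp, Cp, N, internal_coord(.amide$NCA, .amide$angle_C_N_CA, .amide$omega))
  if (tpl$code == "NME") {
    at <- data.frame(name = c("N", "CH3"), element = c("N", "C"),
                     x = c(N[1], CA2[1]), y = c(N[2], CA2[2]), z = c(N[3], CA2[3]),
                     occupancy = 1, altloc = "", hetero = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    C2 <- nerf_place(Cp, N, CA2, internal_coord(.amide$CAC, .amide$angle_N_CA_C, phi))
    at <- .build_from_template(tpl, list(N = N, CA = CA2, C = C2))
  }
  res <- ptm_residue(tpl$code, last$number + 1L, at, "")
  site <- structure(list(chain = chain, resname = NA, resnum = res$number),
                    class = "site_selector")
  ch$residues[[length(ch$residues) + 1L]] <- res
  protein$chains[[ci]] <- ch
  if (tpl$code != "NME") {
    protein <- .set_residue(protein, site, .chi_scan(protein, site, res, tpl))
  }
  protein
}

#' Prepend a residue at the N-terminus of a chain
#'
#' Symmetric to [append_residue()]. `phi` is the phi torsion of the formerly
#' first residue (defined by the new carbonyl carbon) and `psi` the psi
#' torsion of the new residue. On an empty protein or missing chain, a fresh
#' single-residue chain is built in canonical orientation.
#'
#' @inheritParams append_residue
#' @param residue 3-letter code (`"ACE"` caps the N-terminus; N-terminal
#'   acetylation is reachable only this way, not through [modify()]).
#' @return The extended protein.
#' @export
prepend_residue <- function(protein, chain, residue,
                            phi = .beta_phi, psi = .beta_psi) {
  tpl <- residue_template(residue)
  ci <- which(vapply(protein$chains, `[[`, "", "id") == chain)
  if (!length(ci) || !length(protein$chains[[ci]]$residues)) {
    return(.seed_chain(protein, chain, tpl, psi))
  }
  ch <- protein$chains[[ci]]
  first <- ch$residues[[1]]
  g <- function(res, nm) {
    i <- match(nm, res$atoms$name)
    if (is.na(i)) stop("anchor residue lacks backbone atom ", nm)
    as.numeric(res$atoms[i, c("x", "y", "z")])
  }
  Nf <- g(first, "N"); CAf <- g(first, "CA"); Cf <- g(first, "C")
  C0 <- nerf_place(Cf, CAf, Nf, internal_coord(.amide$CN, .amide$angle_C_N_CA, phi))
  O0 <- nerf_place(CAf, Nf, C0, internal_coord(1.231, 122.5, 0))
  CA0 <- nerf_place(CAf, Nf, C0, internal_coord(.amide$CAC, .amide$angle_CAC_N, .amide$omega))
  if (tpl$code == "ACE") {
    at <- data.frame(name = c("CH3", "C", "O"), element = c("C", "C", "O"),
                     x = c(CA0[1], C0[1], O0[1]), y = c(CA0[2], C0[2], O0[2]),
                     z = c(CA0[3], C0[3], O0[3]),
                     occupancy = 1, altloc = "", hetero = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    N0 <- nerf_place(Nf, C0, CA0, internal_coord(.amide$NCA, .amide$angle_N_CA_C, psi))
    at <- .build_from_template(tpl, list(N = N0, CA = CA0, C = C0), psi = psi)
    io <- match("O", at$name)
    at[io, c("x", "y", "z")] <- O0[]  # carbonyl O already fixed by the amide
  }
  res <- ptm_residue(tpl$code, first$number - 1L, at, "")
  ch$residues <- c(list(res), ch$residues)
  protein$chains[[ci]] <- ch
  site <- structure(list(chain = chain, resname = NA, resnum = res$number),
                    class = "site_selector")
  if (!(tpl$code %in% c("ACE", "NME"))) {
    protein <- .set_residue(protein, site, .chi_scan(protein, site, res, tpl))
  }
  protein
}

# build the first residue of a chain in canonical orientation
.seed_chain <- function(protein, chain, tpl, psi) {
  if (tpl$code %in% c("ACE", "NME")) {
    stop("cannot start a chain with the cap residue ", tpl$code)
  }
  at <- .build_from_template(tpl, .canonical_seed(), psi = psi)
  res <- ptm_residue(tpl$code, 1L, at, "")
  ci <- which(vapply(protein$chains, `[[`, "", "id") == chain)
  if (length(ci)) {
    protein$chains[[ci]]$residues <- list(res)
  } else {
    protein$chains[[length(protein$chains) + 1L]] <- ptm_chain(chain, list(res))
  }
  protein
}

#' Build a capped ACE-XXX-NME dipeptide
#'
#' The parameterization model system: the residue of interest flanked by an
#' acetyl and an N-methylamide cap, with its backbone fixed at the
#' alpha-helix (phi, psi = -60, -45) or beta-strand (-135, 135)
#' conformation.
#'
#' @param residue_code 3-letter code of the central residue.
#' @param conformation `"alpha"` or `"beta"`.
#' @param chain Chain id for the new molecule.
#' @return A `ptm_protein` with one three-residue chain.
#' @export
build_dipeptide <- function(residue_code, conformation = c("alpha", "beta"),
                            chain = "A") {
  conformation <- match.arg(conformation)
  pp <- if (conformation == "alpha") c(-60, -45) else c(-135, 135)
  p <- ptm_protein()
  p <- prepend_residue(p, chain, residue_code, psi = pp[2])
  p <- append_residue(p, chain, "NME", psi = pp[2])
  p <- prepend_residue(p, chain, "ACE", phi = pp[1])
  p
}

#' Measure the backbone phi/psi torsions of a residue
#'
#' @param protein A `ptm_protein`.
#' @param site Site string or selector.
#' @return Named numeric vector `c(phi =, psi =)`; entries are `NA` at chain
#'   termini where the torsion is undefined.
#' @export
backbone_torsions <- function(protein, site) {
  if (is.character(site)) site <- parse_site(site)
  idx <- .residue_index(protein, site)
  ch <- protein$chains[[idx[1]]]
  res <- ch$residues[[idx[2]]]
  g <- function(r, nm) {
    i <- match(nm, r$atoms$name)
    if (is.na(i)) return(NULL)
    as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  N <- g(res, "N"); CA <- g(res, "CA"); C <- g(res, "C")
  phi <- psi <- NA_real_
  if (idx[2] > 1) {
    prevC <- g(ch$residues[[idx[2] - 1]], "C")
    if (!is.null(prevC) && !is.null(N) && !is.null(CA) && !is.null(C)) {
      phi <- dihedral_angle(prevC, N, CA, C)
    }
  }
  if (idx[2] < length(ch$residues)) {
    nextN <- g(ch$residues[[idx[2] + 1]], "N")
    if (!is.null(nextN) && !is.null(N) && !is.null(CA) && !is.null(C)) {
      psi <- dihedral_angle(N, CA, C, nextN)
    }
  }
  c(phi = phi, psi = psi)
}
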