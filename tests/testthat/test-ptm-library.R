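test_that("the modification registry matches the published table literally", {
  reg <- list_modifications()
  expect_equal(sort(unique(reg$amino_acid)),
               c("ARG", "ASP", "CYS", "GLU", "HIS", "LYS", "SER", "THR", "TYR"))
  cys <- list_modifications("CYS")$reaction
  expect_length(cys, 11)
  expect_setequal(cys, c("Carbamylation (carbamoylation)", "Cyanylation",
                         "Cysteinylation", "Glutathionylation", "Methylation",
                         "Nitrosylation (nitrosation)", "Phosphorylation",
                         "Sulfenylation", "Sulfhydration", "Sulfinylation",
                         "Sulfonylation"))
  expect_equal(list_modifications("TYR")$reaction, "Phosphorylation")
  expect_setequal(list_modifications("ARG")$reaction,
                  c("Methylation", "Symmetric demethylation",
                    "Asymmetric demethylation", "Phosphorylation"))
  expect_setequal(list_modifications("LYS")$reaction,
                  c("Acetylation", "Methylation", "Dimethylation",
                    "Trimethylation", "Phosphorylation"))
  expect_equal(nrow(list_modifications("GLY")), 0)
})

test_that("mutate keeps the backbone fixed and rebuilds the side chain", {
  p <- make_toy_protein(3, c("ALA", "CYS", "ALA"))
  p$chains[[1]]$residues[[2]]$number <- 155L
  p$chains[[1]]$residues[[3]]$number <- 156L
  pm <- mutate(p, "A:CYS155", "MET")
  r <- find_residue(pm, "A:MET155")
  expect_equal(r$name, "MET")
  bb <- c("N", "CA", "C", "O")
  old <- find_residue(p, "A:155")$atoms
  expect_equal(as.matrix(r$atoms[match(bb, r$atoms$name), c("x", "y", "z")]),
               as.matrix(old[match(bb, old$name), c("x", "y", "z")]),
               tolerance = 1e-9)
  # other residues untouched
  for (n in c(1L, 156L)) {
    expect_equal(find_residue(pm, paste0("A:", n))$atoms,
                 find_residue(p, paste0("A:", n))$atoms)
  }
  expect_error(mutate(p, "A:155", "ZZZ"), "unknown residue template")
})

test_that("identity mutation leaves coordinates essentially unchanged", {
  p <- make_toy_protein(1, "CYS")
  pm <- mutate(p, "A:CYS1", "CYS")
  r0 <- find_residue(p, "A:1")$atoms
  r1 <- find_residue(pm, "A:1")$atoms
  expect_equal(r1$name, r0$name)
  bb <- c("N", "CA", "C", "O")
  expect_equal(as.matrix(r1[match(bb, r1$name), c("x", "y", "z")]),
               as.matrix(r0[match(bb, r0$name), c("x", "y", "z")]),
               tolerance = 1e-9)
})

test_that("mutation into a crowded pocket keeps the least-clash rotamer", {
  p <- make_toy_protein(3, c("ALA", "ALA", "ALA"))
  # cage of carbons around residue 2's side-chain region
  cb <- find_residue(p, "A:2")$atoms
  cb <- as.numeric(cb[cb$name == "CB", c("x", "y", "z")])
  set.seed(9)
  cage <- t(vapply(1:40, function(i) {
    u <- rnorm(3); u / sqrt(sum(u^2)) * runif(1, 2.5, 4.5) + cb
  }, numeric(3)))
  p$chains[[2]] <- ptm_chain("X", list(
    bare_residue("UNK", 1, cage, "C", paste0("C", 1:40))))
  expect_warning(pm <- mutate(p, "A:2", "MET"), "clash")
  got <- find_residue(pm, "A:MET2")
  side <- got$atoms[!(got$atoms$name %in% c("N", "CA", "C", "O")), ]
  got_n <- count_clashes(pm, side, exclude_sites = list(c("A", 2)))
  # exhaustive 12x12 oracle over the same grid
  tpl <- residue_template("MET")
  base <- find_residue(suppressWarnings(mutate(p, "A:2", "MET")), "A:2")
  best <- Inf
  for (d1 in seq(0, 330, 30)) {
    for (d2 in seq(0, 330, 30)) {
      cand <- ptmforge:::.set_chis(base, tpl, chi1 = 180 + d1, chi2 = 180 + d2)
      sc <- cand$atoms[!(cand$atoms$name %in% c("N", "CA", "C", "O")), ]
      best <- min(best, count_clashes(p, sc, exclude_sites = list(c("A", 2))))
    }
  }
  expect_equal(got_n, best)
  expect_gt(best, 0)
})

test_that("modify builds the documented products", {
  # serine acetylation (worked example): SER atoms retained, acetyl appended
  p <- make_toy_protein(2, c("SER", "ALA"))
  p$chains[[1]]$residues[[1]]$number <- 154L
  p$chains[[1]]$residues[[2]]$number <- 155L
  pa <- modify(p, "A:SER154", "acetylation")
  r <- find_residue(pa, "A:154")
  old_names <- find_residue(p, "A:154")$atoms$name
  expect_true(all(old_names %in% r$atoms$name))
  expect_true(all(c("CX", "OX", "CMX") %in% r$atoms$name))

  # cysteine nitrosylation: product SNC with S-N-O chain
  snc <- ptm_protein()
  snc <- prepend_residue(snc, "A", "CYS")
  snc <- modify(snc, "A:CYS1", "nitrosylation")
  r <- find_residue(snc, "A:SNC1")
  expect_equal(r$name, "SNC")
  expect_true(all(c("ND", "OE") %in% r$atoms$name))
  bd <- detect_bonds(r$atoms)
  key <- function(i, j) paste(sort(r$atoms$name[c(i, j)]), collapse = "-")
  bonded <- mapply(key, bd$i, bd$j)
  expect_true("ND-SG" %in% bonded)
  expect_true("ND-OE" %in% bonded)

  # the alias spelling is accepted
  snc2 <- prepend_residue(ptm_protein(), "A", "CYS")
  expect_equal(find_residue(modify(snc2, "A:CYS1", "nitrosation"), "A:1")$name,
               "SNC")

  expect_error(modify(make_toy_protein(1, "GLY"), "A:1", "phosphorylation"),
               "no reactions")
  expect_error(modify(make_toy_protein(1, "SER"), "A:1", "nitrosylation"),
               "valid reactions")
})

test_that("every cysteine modify product is connected in its bonded graph", {
  reactions <- c("carbamylation", "cyanylation", "cysteinylation",
                 "glutathionylation", "methylation", "nitrosylation",
                 "phosphorylation", "sulfenylation", "sulfhydration",
                 "sulfinylation", "sulfonylation")
  for (rx in reactions) {
    p <- prepend_residue(ptm_protein(), "A", "CYS")
    pm <- suppressWarnings(modify(p, "A:CYS1", rx))
    r <- find_residue(pm, "A:1")
    bd <- detect_bonds(r$atoms)
    n <- nrow(r$atoms)
    adj <- matrix(FALSE, n, n)
    adj[cbind(bd$i, bd$j)] <- TRUE; adj[cbind(bd$j, bd$i)] <- TRUE
    seen <- 1L
    repeat {
      grown <- unique(c(seen, which(colSums(adj[seen, , drop = FALSE]) > 0)))
      if (length(grown) == length(seen)) break
      seen <- grown
    }
    expect_length(seen, n)
  }
})

test_that("prepend/append build capped termini and honour explicit torsions", {
  p <- prepend_residue(ptm_protein(), "A", "CYS")
  expect_length(p$chains, 1)
  expect_equal(find_residue(p, "A:CYS1")$name, "CYS")

  capped <- prepend_residue(p, "A", "ACE")
  capped <- append_residue(capped, "A", "NME")
  ace <- capped$chains[[1]]$residues[[1]]
  nme <- capped$chains[[1]]$residues[[length(capped$chains[[1]]$residues)]]
  expect_equal(ace$name, "ACE")
  expect_equal(nme$name, "NME")
  expect_setequal(ace$atoms$name, c("CH3", "C", "O"))
  expect_setequal(nme$atoms$name, c("N", "CH3"))

  tor <- make_toy_protein(2, c("ALA", "ALA"))
  tor <- append_residue(tor, "A", "GLY", phi = -60, psi = -45)
  pp <- backbone_torsions(tor, "A:GLY3")
  expect_equal(unname(pp["phi"]), -60, tolerance = 1e-6)
  expect_equal(unname(backbone_torsions(tor, "A:ALA2")["psi"]), -45,
               tolerance = 1e-6)
  expect_error(append_residue(tor, "A", "ZZZ"), "unknown residue template")
})

test_that("capped dipeptides fix the requested backbone conformation", {
  for (case in list(list("alpha", c(-60, -45)), list("beta", c(-135, 135)))) {
    d <- build_dipeptide("SNC", case[[1]])
    pp <- backbone_torsions(d, "A:SNC1")
    expect_equal(unname(pp), case[[2]], tolerance = 1e-6)
    n_expect <- length(residue_template("ACE")$atom_names) +
      length(residue_template("SNC")$atom_names) +
      length(residue_template("NME")$atom_names)
    expect_equal(nrow(protein_atoms(d)), n_expect)
  }
})
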