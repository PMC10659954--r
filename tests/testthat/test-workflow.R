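test_that("the default TI schedule has 13 lambdas per stage and 25 legs", {
  s <- gen_ti_schedule()
  expect_length(s$stages, 2)
  expect_equal(s$stages$electrostatic,
               c(0, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80,
                 0.90, 0.95, 1.00))
  expect_length(s$stages[[1]], 13)
  expect_equal(nrow(s$legs), 25)
  expect_equal(s$leg_ns, 1)
  expect_equal(names(s$stages), c("electrostatic", "vdw-bonded"))
})

test_that("custom lambda ladders are validated and legs counted correctly", {
  one <- gen_ti_schedule(c(0, 0.5, 1), stages = "electrostatic")
  expect_equal(nrow(one$legs), 3)
  expect_error(gen_ti_schedule(c(0, 0.7, 0.3, 1)), "increasing")
  expect_error(gen_ti_schedule(c(0.1, 0.5, 1)), "start at 0")
  # shared-boundary rule: legs = 2 * n - 1 for two stages, any ladder size
  for (n in c(3, 7, 13)) {
    lam <- seq(0, 1, length.out = n)
    expect_equal(nrow(gen_ti_schedule(lam)$legs), 2 * n - 1)
  }
})

test_that("equilibration defaults: ladder, 20 ns NPT, overridable buffer", {
  prot <- make_toy_protein(3, c("ALA", "CYS", "GLY"))
  md <- gen_equilibration_protocol(prot)
  expect_equal(md$minimization_ladder, c(1000, 500, 200, 100, 10, 5, 1))
  expect_equal(md$npt$ns, 20)
  expect_equal(md$nvt$ps, 500)
  expect_equal(md$nvt$temperature_K, 300)
  expect_equal(md$timestep_fs, 2)
  expect_equal(md$box$type, "dodecahedron")
  expect_equal(md$box$buffer_nm, 1)
  expect_s3_class(md$ions, "ion_plan")

  ov <- gen_equilibration_protocol(prot, box_buffer_nm = 1.2)
  expect_true(any(grepl("-d 1.2", ov$script, fixed = TRUE)))
  expect_error(gen_equilibration_protocol(prot, ladder = c(100, 200)),
               "decreasing")
  expect_error(gen_equilibration_protocol(prot, npt_ns = -1), "positive")
})

test_that("QM decks annotate both conformers with the documented setups", {
  decks <- gen_qm_decks("SNC")
  expect_length(decks$conformers, 2)
  expect_equal(decks$conformers$alpha$phi_psi, c(-60, -45))
  expect_equal(decks$conformers$beta$phi_psi, c(-135, 135))
  geo <- decks$conformers$alpha$geometry
  expect_true(any(grepl("r2SCAN-D3(BJ)", geo, fixed = TRUE)))
  expect_true(any(grepl("def2-TZVP", geo)))
  expect_true(any(grepl("120", geo)))
  esp <- decks$conformers$beta$esp
  expect_true(any(grepl("6-31G\\*", esp)))
  expect_true(any(grepl("ACE", esp)) && any(grepl("NME", esp)))
  scan <- decks$conformers$alpha$scan
  expect_equal(sum(grepl("^freeze dihedral", scan)), 3)
  expect_error(gen_qm_decks("ZZZ"), "unknown residue template")
})

test_that("torsion-fit configurations carry the documented restraints", {
  prof <- torsion_profile(c("CA", "CB", "SG", "ND"), seq(-180, 165, 15),
                          qm = rep(0, 24))
  cfg <- gen_torsion_fit_config(prof)
  expect_gte(cfg$dihedral_restraint, 14000)
  expect_equal(cfg$position_restraint, 418)
  ov <- gen_torsion_fit_config(prof, position_restraint = 500)
  expect_true(any(grepl("restraint position 500", ov$text)))
  expect_error(gen_torsion_fit_config(list()), "at least one")
})

test_that("docking configs default to exhaustiveness 64 and clamp two-ligand boxes", {
  box <- list(center = c(0, 0, 0), size = c(10, 10, 10))
  cfg <- gen_docking_config("receptor.pdbqt", "lig1.pdbqt", box = box)
  expect_equal(cfg$exhaustiveness, 64L)
  expect_false(cfg$multi_ligand)
  expect_equal(cfg$box$size, c(10, 10, 10))

  two <- gen_docking_config("receptor.pdbqt", c("ga3p.pdbqt", "nadp.pdbqt"),
                            box = box)
  expect_true(two$multi_ligand)
  expect_equal(two$box$size, c(19, 27, 16))
  big <- gen_docking_config("receptor.pdbqt", c("a", "b"),
                            box = list(center = c(0, 0, 0), size = c(30, 30, 30)))
  expect_equal(big$box$size, c(30, 30, 30))

  expect_error(gen_docking_config("receptor.pdbqt", "lig1.pdbqt"),
               "supply the box")
  annotated <- structure("receptor.pdbqt",
                         site = list(center = c(1, 2, 3), size = c(12, 12, 12)))
  auto <- gen_docking_config(annotated, "lig1.pdbqt")
  expect_equal(auto$box$center, c(1, 2, 3))
})

test_that("batch scripts are deterministic and fully overridable", {
  s1 <- gen_batch_script(c("echo hi"))
  s2 <- gen_batch_script(c("echo hi"))
  expect_identical(s1, s2)
  expect_true(grepl("#SBATCH --job-name", s1))
  custom <- gen_batch_script(c("echo hi"), partition = "bigmem")
  expect_true(grepl("--partition=bigmem", custom))
  plain <- gen_batch_script(c("echo hi"), scheduler = "none")
  expect_false(grepl("#SBATCH", plain))
  inf <- gen_inference_script("seqs.fasta")
  expect_true(grepl("placeholder; not executed", inf))
  expect_true(grepl("run_inference seqs.fasta", inf))
})

test_that("generators are pure: identical inputs give identical text", {
  prot <- make_toy_protein(2, c("ALA", "GLY"))
  expect_identical(gen_equilibration_protocol(prot)$script,
                   gen_equilibration_protocol(prot)$script)
  expect_identical(gen_qm_decks("CYS"), gen_qm_decks("CYS"))
  box <- list(center = c(0, 0, 0), size = c(20, 20, 20))
  expect_identical(gen_docking_config("r", c("a", "b"), box),
                   gen_docking_config("r", c("a", "b"), box))
})
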