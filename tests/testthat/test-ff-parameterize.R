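test_that("Seminario bond constants recover analytic force fields", {
  # diatomic: exact recovery
  pos <- rbind(A = c(0, 0, 0), B = c(1, 0, 0))
  h <- make_harmonic_hessian(pos, bonds = data.frame(i = 1, j = 2, kb = 1000))
  b <- seminario_bond(h, 1, 2)
  expect_equal(b$kb, 1000, tolerance = 1e-6)
  expect_equal(b$req, 0.1, tolerance = 1e-9)
  # water-like triatomic: both stretches within 1%
  hw <- water_hessian()
  expect_equal(seminario_bond(hw, 2, 1)$kb, 4e5, tolerance = 0.01)
  expect_equal(seminario_bond(hw, 3, 1)$kb, 5e5, tolerance = 0.01)
  # degenerate sub-block
  hz <- h
  hz$hessian[1:3, 4:6] <- 0; hz$hessian[4:6, 1:3] <- 0
  expect_error(seminario_bond(hz, 1, 2), "degenerate")
})

test_that("Seminario angle constants recover analytic force fields", {
  hw <- water_hessian(ktheta = 500)
  a <- seminario_angle(hw, 2, 1, 3)
  expect_equal(a$k_theta, 500, tolerance = 0.01)
  expect_equal(a$theta_eq, 104.5, tolerance = 1e-6)
  expect_false(a$corrected)     # lone angle: no sibling shares the center
  # theta_eq equals the directly measured angle
  m <- measure_internal(hw$positions[2, ] + c(0, 0, 1), hw$positions[2, ],
                        hw$positions[1, ], hw$positions[3, ])
  expect_equal(a$theta_eq, m$theta, tolerance = 1e-9)
  # chain with two angles at different centers: both recovered
  hc <- chain_hessian()
  expect_equal(seminario_angle(hc, 1, 2, 3)$k_theta, 600, tolerance = 0.01)
  expect_equal(seminario_angle(hc, 2, 3, 4)$k_theta, 350, tolerance = 0.01)
  # sibling bookkeeping: shared center flags the correction
  all_ang <- rbind(c(1, 2, 3), c(2, 3, 4))
  expect_false(seminario_angle(hc, 1, 2, 3, angles = all_ang)$corrected)
  pos4 <- rbind(A = c(1.5, 0, 0), B = c(0, 0, 0), C = c(-0.6, 1.4, 0),
                D = c(-0.6, -0.7, 1.2))
  hb <- make_harmonic_hessian(
    pos4, bonds = data.frame(i = c(1, 3, 4), j = c(2, 2, 2), kb = c(3e5, 3e5, 3e5)),
    angles = data.frame(i = c(1, 1, 3), j = c(2, 2, 2), k = c(3, 4, 4),
                        k_theta = c(400, 450, 500)))
  star <- rbind(c(1, 2, 3), c(1, 2, 4), c(3, 2, 4))
  expect_true(seminario_angle(hb, 1, 2, 3, angles = star)$corrected)
  expect_error(seminario_angle(hw, 2, 1, 2), "collinear|degenerate")
})

test_that("conformer averaging is order-independent", {
  h1 <- water_hessian(kb1 = 4e5)
  h2 <- water_hessian(kb1 = 4.4e5, theta_deg = 106)
  ab <- seminario_bond(list(h1, h2), 2, 1)
  ba <- seminario_bond(list(h2, h1), 2, 1)
  expect_equal(ab$kb, ba$kb)
  expect_equal(ab$req, ba$req)
  aa <- seminario_angle(list(h1, h2), 2, 1, 3)
  expect_equal(aa$theta_eq, mean(c(104.5, 106)), tolerance = 1e-6)
  expect_equal(seminario_angle(list(h2, h1), 2, 1, 3)$k_theta, aa$k_theta)
})

test_that("RESP recovers generating charges from exact Coulomb ESP", {
  one <- data.frame(name = "A", element = "C", x = 0, y = 0, z = 0)
  s1 <- make_point_charge_esp(one, 0.5, n_points = 200, seed = 3)
  f1 <- resp_fit(s1, total_charge = 0.5, restraint_a = 0)
  expect_equal(unname(f1$charges), 0.5, tolerance = 1e-6)

  two <- data.frame(name = c("A", "B"), element = "C",
                    x = c(0, 3), y = 0, z = 0)
  s2 <- make_point_charge_esp(two, c(0.3, -0.3), n_points = 300, seed = 7)
  f2 <- resp_fit(s2, total_charge = 0, restraint_a = 0)
  expect_equal(unname(f2$charges), c(0.3, -0.3), tolerance = 1e-4)
  expect_lt(abs(f2$total), 1e-12)
})

test_that("RESP honours group constraints and multi-conformer input", {
  atoms <- data.frame(name = c("A", "B", "C1"), element = "C",
                      x = c(0, 3, 5.5), y = c(0, 0.5, 0), z = 0)
  qs <- c(0.25, -0.4, 0.15)
  sa <- make_point_charge_esp(atoms, qs, n_points = 400, seed = 1,
                              conformer = "alpha")
  atoms2 <- atoms; atoms2$y <- c(0, -0.5, 0.3)
  sb <- make_point_charge_esp(atoms2, qs, n_points = 400, seed = 2,
                              conformer = "beta")
  fit <- resp_fit(list(sa, sb),
                  constraints = list(list(atoms = c("A", "B"), total = -0.15)),
                  total_charge = 0, restraint_a = 0.0005)
  expect_equal(unname(fit$charges["A"] + fit$charges["B"]), -0.15,
               tolerance = 1e-10)
  expect_equal(fit$total, 0, tolerance = 1e-12)
  expect_error(
    resp_fit(sa, constraints = list(list(atoms = c("A", "B", "C1"), total = 5)),
             total_charge = 0),
    "infeasible")
})

test_that("two-stage RESP refit enforces stage-2 equivalences", {
  atoms <- data.frame(name = c("CT", "H1A", "H1B"), element = c("C", "H", "H"),
                      x = c(0, 1.0, -0.5), y = c(0, 0.3, 0.9), z = 0)
  s <- make_point_charge_esp(atoms, c(-0.2, 0.12, 0.08), n_points = 400, seed = 5)
  fit <- resp_fit(s, total_charge = 0,
                  stage2_atoms = c("H1A", "H1B"),
                  stage2_equiv = list(c("H1A", "H1B")))
  expect_equal(unname(fit$charges["H1A"]), unname(fit$charges["H1B"]))
  expect_equal(fit$total, 0, tolerance = 1e-12)
})

test_that("torsion-series fitting recovers generators and reports residuals", {
  ts <- torsion_series(c("A", "B", "C", "D"),
                       data.frame(k_phi = 2.0, n = 1, phi_s = 0))
  pr <- make_torsion_profile(ts, seq(-180, 165, by = 15))
  fit <- fit_torsion_series(pr, multiplicities = 1:3)
  expect_equal(fit$terms$k_phi[fit$terms$n == 1], 2.0, tolerance = 1e-6)
  expect_lt(max(fit$terms$k_phi[fit$terms$n != 1]), 1e-9)
  expect_lt(attr(fit, "residual_rms"), 1e-9)

  flat <- torsion_profile(c("A", "B", "C", "D"), seq(-180, 165, 15),
                          qm = rep(1, 24))
  ffit <- fit_torsion_series(flat, 1:3)
  expect_lt(max(ffit$terms$k_phi), 1e-12)

  # self-consistency against the bundled published series
  snc <- bundled_snc_parameters()
  csno <- snc$torsions[[which(vapply(snc$torsions, function(t) {
    identical(t$atoms, c("CB", "SG", "ND", "OE"))
  }, TRUE))]]
  prof <- make_torsion_profile(csno, seq(-180, 170, by = 10))
  refit <- fit_torsion_series(prof, multiplicities = 1:4)
  ord <- match(csno$terms$n, refit$terms$n)
  expect_equal(refit$terms$k_phi[ord], csno$terms$k_phi, tolerance = 1e-3)
  expect_equal(refit$terms$phi_s[ord], csno$terms$phi_s)

  expect_error(fit_torsion_series(
    torsion_profile(c("A", "B", "C", "D"), seq(0, 165, 15), qm = rep(0, 12)),
    multiplicities = 1:20), "fewer grid points")
})

test_that("fitted series reproduce the generating curve", {
  gen <- torsion_series(c("A", "B", "C", "D"),
                        data.frame(k_phi = c(0.8, 2.5), n = c(1, 3),
                                   phi_s = c(180, 0)))
  profs <- list(make_torsion_profile(gen, seq(-180, 165, 15), "alpha"),
                make_torsion_profile(gen, seq(-172, 173, 15), "beta"))
  fit <- fit_torsion_series(profs, 1:4)
  grid <- seq(-180, 179, 1)
  expect_lt(sqrt(mean((eval_torsion(fit, grid) - eval_torsion(gen, grid))^2)),
            1e-6)
})

test_that("closed-form term evaluation matches hand arithmetic", {
  snc <- bundled_snc_parameters()
  no <- snc$bonds[[which(vapply(snc$bonds, function(b) {
    identical(b$atoms, c("ND", "OE"))
  }, TRUE))]]
  expect_equal(eval_bond(no, no$req), 0)
  expect_equal(eval_bond(no, 0.1270), 0.5 * 695768.8 * 0.01^2)
  ang <- snc$angles[[4]]
  expect_equal(eval_angle(ang, ang$theta_eq), 0)
  csno <- snc$torsions[[3]]
  expect_equal(eval_torsion(csno, 0), 2 * 1.0769)
  # periodicity and non-negativity
  grid <- seq(-180, 179, 7)
  expect_equal(eval_torsion(csno, grid), eval_torsion(csno, grid + 360),
               tolerance = 1e-12)
  expect_true(all(eval_torsion(csno, grid) >= 0))
})

test_that("the bundled SNC parameter set equals the published tables", {
  snc <- bundled_snc_parameters()
  expect_equal(snc$charges,
               c(CA = -0.0218, HA = 0.0758, CB = 0.4533, HB1 = -0.0674,
                 HB2 = -0.0674, SG = -0.1959, ND = 0.0855, OE = -0.1468))
  req <- vapply(snc$bonds, `[[`, 0, "req")
  kb <- vapply(snc$bonds, `[[`, 0, "kb")
  expect_equal(req, c(0.1803, 0.1918, 0.1170))
  expect_equal(kb, c(129555.1, 79743.2, 695768.8))
  expect_equal(vapply(snc$angles, `[[`, 0, "theta_eq"),
               c(107.5, 113.8, 99.5, 117.2))
  expect_equal(vapply(snc$angles, `[[`, 0, "k_theta"),
               c(293.0, 487.5, 1137.0, 1283.1))
  csno <- snc$torsions[[3]]
  expect_equal(nrow(csno$terms), 4)
  expect_equal(csno$terms$k_phi, c(1.0769, 27.2930, 2.7214, 0.5033))
  expect_equal(csno$terms$n, c(1, 2, 3, 4))
  expect_equal(csno$terms$phi_s, c(0, 180, 180, 180))
})

test_that("parameter include files round-trip and omit empty sections", {
  snc <- bundled_snc_parameters()
  d <- tempfile("itp")
  paths <- write_parameter_files(snc, d)
  txt <- readLines(paths[2])
  expect_true(any(grepl("^\\s*SG\\s+ND\\s+1\\s+0\\.1918\\s+79743\\.2", txt)))
  back <- read_parameter_files(d, "SNC")
  expect_equal(back$charges[names(snc$charges)], snc$charges)
  for (i in seq_along(snc$bonds)) {
    expect_equal(back$bonds[[i]]$req, snc$bonds[[i]]$req)
    expect_equal(back$bonds[[i]]$kb, snc$bonds[[i]]$kb)
  }
  for (i in seq_along(snc$angles)) {
    expect_equal(back$angles[[i]]$k_theta, snc$angles[[i]]$k_theta)
  }
  for (i in seq_along(snc$torsions)) {
    expect_equal(back$torsions[[i]]$terms$k_phi, snc$torsions[[i]]$terms$k_phi)
    expect_equal(back$torsions[[i]]$terms$phi_s, snc$torsions[[i]]$terms$phi_s)
  }
  # no dihedral section when the torsion list is empty
  bare <- parameter_set("XXX", c(CA = 0.1, CB = -0.1),
                        bonds = snc$bonds[1],
                        atom_types = c(CA = "CT", CB = "CT"))
  paths2 <- write_parameter_files(bare, tempfile("itp2"))
  expect_false(any(grepl("dihedraltypes", readLines(paths2[2]))))
  # unmapped atom type errors
  bad <- parameter_set("YYY", c(QQ = 0.1), atom_types = c(CA = "CT"))
  expect_error(write_parameter_files(bad, tempfile()), "unmapped")
})
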