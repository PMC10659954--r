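test_that("NERF places planar cis and trans points exactly", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); cc <- c(1, 1, 0)
  expect_equal(nerf_place(a, b, cc, internal_coord(1, 90, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(nerf_place(a, b, cc, internal_coord(1, 90, 180)), c(2, 1, 0),
               tolerance = 1e-12)
  expect_error(nerf_place(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                          internal_coord(1, 90, 0)), "collinear")
})

test_that("measure_internal reports cis as 0 and trans as +180", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); cc <- c(1, 1, 0)
  expect_equal(measure_internal(a, b, cc, c(0, 1, 0))$phi, 0)
  expect_equal(measure_internal(a, b, cc, c(2, 1, 0))$phi, 180)
  expect_error(measure_internal(a, a, cc, c(2, 1, 0)), "coincident")
})

test_that("nerf_place and measure_internal are mutually inverse", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    repeat {
      a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
      ab <- b - a; bc <- cc - b
      cr <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
              ab[1] * bc[2] - ab[2] * bc[1])
      if (sqrt(sum(cr^2)) > 1e-3) break
    }
    r <- runif(1, 0.8, 2); th <- runif(1, 10, 170); ph <- runif(1, -179.5, 179.5)
    m <- measure_internal(a, b, cc, nerf_place(a, b, cc, internal_coord(r, th, ph)))
    worst <- max(worst, abs(m$r - r), abs(m$theta - th), abs(m$phi - ph))
  }
  expect_lt(worst, 1e-6)
})

test_that("superposition recovers rigid transforms and is exact for copies", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  id <- superpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Y <- sweep(X %*% t(R), 2, c(1, -2, 0.5), `+`)
  s <- superpose(X, Y)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$rotation, R, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("noisy superposition is close to a brute-force rotation search", {
  set.seed(11)
  X <- matrix(rnorm(150), 50, 3)
  Y <- X + matrix(rnorm(150, 0, 0.1), 50, 3)
  fit <- superpose(X, Y)
  # brute force over a dense grid of small rotations about random axes,
  # centered data (independent oracle for the minimal rmsd)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  for (k in 1:2000) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -0.2, 0.2)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    best <- min(best, sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2))))
  }
  expect_lt(fit$rmsd, best + 1e-12)
  expect_gt(fit$rmsd, best * 0.8)
})

test_that("dihedral rotation preserves geometry and composes to identity", {
  p <- make_toy_protein(1, "MET")
  res <- find_residue(p, "A:MET1")
  moving <- c("SD", "CE")
  r0 <- rotate_dihedral(res, c("CB", "CG"), 0, moving)
  expect_equal(r0$atoms, res$atoms, tolerance = 1e-12)
  r360 <- rotate_dihedral(res, c("CB", "CG"), 360, moving)
  expect_equal(as.matrix(r360$atoms[, c("x", "y", "z")]),
               as.matrix(res$atoms[, c("x", "y", "z")]), tolerance = 1e-9)
  r12 <- res
  for (i in 1:12) r12 <- rotate_dihedral(r12, c("CB", "CG"), 30, moving)
  expect_equal(as.matrix(r12$atoms[, c("x", "y", "z")]),
               as.matrix(res$atoms[, c("x", "y", "z")]), tolerance = 1e-8)
  # intra-set bond lengths preserved
  d0 <- dist(as.matrix(res$atoms[match(moving, res$atoms$name), c("x", "y", "z")]))
  r30 <- rotate_dihedral(res, c("CB", "CG"), 30, moving)
  d1 <- dist(as.matrix(r30$atoms[match(moving, r30$atoms$name), c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_error(rotate_dihedral(res, c("CB", "QQ"), 30, moving), "not found")
})

test_that("bond perception follows the 120% covalent-radius criterion", {
  cs <- data.frame(element = c("C", "S"), x = c(0, 1.803), y = 0, z = 0)
  expect_equal(nrow(detect_bonds(cs)), 1)
  sn <- data.frame(element = c("S", "N"), x = c(0, 1.918), y = 0, z = 0)
  expect_equal(nrow(detect_bonds(sn)), 1)
  far <- data.frame(element = c("C", "C"), x = c(0, 3), y = 0, z = 0)
  expect_equal(nrow(detect_bonds(far)), 0)
  expect_error(detect_bonds(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "Xx")
})

test_that("bond perception is invariant under reordering and rigid motion", {
  set.seed(3)
  p <- make_toy_protein(2, c("CYS", "SER"))
  at <- protein_atoms(p)[, c("element", "x", "y", "z")]
  b0 <- detect_bonds(at)
  perm <- sample(nrow(at))
  bp <- detect_bonds(at[perm, ])
  canon <- function(b, map = seq_len(nrow(at))) {
    pairs <- cbind(map[b$i], map[b$j])
    sorted <- t(apply(pairs, 1, sort))
    sorted[order(sorted[, 1], sorted[, 2]), , drop = FALSE]
  }
  expect_equal(canon(bp, perm), canon(b0))
  th <- 1; R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                       3, 3, byrow = TRUE)
  at2 <- at
  at2[, c("x", "y", "z")] <- sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(R),
                                   2, c(5, -3, 2), `+`)
  expect_equal(detect_bonds(at2), b0)
})

test_that("clash counting uses vdW overlap, exclusions, and heavy atoms only", {
  prot <- bare_protein(ptm_chain("A", list(
    bare_residue("ALA", 1, c(0, 0, 0), "C", "CA"))))
  cand <- data.frame(name = "CX", element = "C", x = 0.5, y = 0, z = 0)
  expect_equal(count_clashes(prot, cand), 1L)
  far <- data.frame(name = "CX", element = "C", x = 5, y = 0, z = 0)
  expect_equal(count_clashes(prot, far), 0L)
  excl <- data.frame(cand_name = "CX", chain = "A", resnum = 1, atom_name = "CA")
  expect_equal(count_clashes(prot, cand, exclusions = excl), 0L)
  hyd <- data.frame(name = "HX", element = "H", x = 0.5, y = 0, z = 0)
  expect_equal(count_clashes(prot, hyd), 0L)
  expect_equal(count_clashes(prot, cand[0, ]), 0L)
  # monotone non-increasing along a separating direction
  counts <- vapply(seq(0.5, 4, by = 0.25), function(d) {
    count_clashes(prot, data.frame(name = "CX", element = "C",
                                   x = d, y = 0, z = 0))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
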