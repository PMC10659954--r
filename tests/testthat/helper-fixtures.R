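# Shared fixture builders for the test suite (everything is generated in
# code; no binary data).

# water-like triatomic at equilibrium with known diagonal force field
water_hessian <- function(kb1 = 4e5, kb2 = 5e5, ktheta = 500,
                          theta_deg = 104.5, r = 0.957) {
  th <- theta_deg * pi / 180
  pos <- rbind(O = c(0, 0, 0), H1 = c(r, 0, 0),
               H2 = r * c(cos(th), sin(th), 0))
  make_harmonic_hessian(
    pos,
    bonds = data.frame(i = c(2, 3), j = c(1, 1), kb = c(kb1, kb2)),
    angles = data.frame(i = 2, j = 1, k = 3, k_theta = ktheta))
}

# four-atom chain with two bonds-plus-angles force field (no shared center)
chain_hessian <- function(kb = c(3e5, 2e5, 4e5), ktheta = c(600, 350)) {
  pos <- rbind(A = c(0, 0, 0), B = c(1.5, 0, 0),
               C = c(2.2, 1.3, 0), D = c(3.6, 1.5, 0.4))
  make_harmonic_hessian(
    pos,
    bonds = data.frame(i = 1:3, j = 2:4, kb = kb),
    angles = data.frame(i = c(1, 2), j = c(2, 3), k = c(3, 4),
                        k_theta = ktheta))
}

# minimal protein built directly from residues with arbitrary atoms
bare_protein <- function(...) {
  ptm_protein(list(...))
}

bare_residue <- function(name, number, xyz, elements = "C",
                         atom_names = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(n))
  ptm_residue(name, number,
              data.frame(name = atom_names,
                         element = rep_len(elements, n),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}
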