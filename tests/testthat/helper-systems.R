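# shared builders for the test suite

# three heavy atoms with mixed first/second neighbour orders; matches the
# frozen independent-oracle values in test-sasa_solvation.R
three_atom_system <- function() {
  top <- topology(
    data.frame(name = c("O", "CA", "CB"),
               sasa_type = c("O", "CH1", "CH3"),
               resid = 1, resname = "X", stringsAsFactors = FALSE),
    rbind(c(1L, 2L), c(2L, 3L)))
  list(top = top, xyz = rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.15, 0.2, 0)))
}

# complete toy force field over a chain topology
chain_forcefield <- function(top, with_sasa = FALSE) {
  toy_forcefield(
    bonds = data.frame(i = top$bonds[, 1], j = top$bonds[, 2],
                       b0 = 0.15, kb = 1e5),
    angles = data.frame(i = 1, j = 2, k = 3, theta0 = 111, ktheta = 500),
    torsions = data.frame(i = 1, j = 2, k = 3, l = 4,
                          mult = 3, phase = 30, kphi = 5),
    lj = data.frame(c6 = rep(0.002, n_atoms(top)), c12 = 2e-6),
    charges = rep(c(0.2, -0.2), length.out = n_atoms(top)),
    sasa = if (with_sasa) list(params = sasa_params()) else NULL)
}

# proper random rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# central finite-difference forces of any energy functional
fd_forces <- function(xyz, energy_fn, h = 1e-6) {
  g <- xyz * 0
  for (i in seq_len(nrow(xyz))) for (k in 1:3) {
    xp <- xyz; xp[i, k] <- xp[i, k] + h
    xm <- xyz; xm[i, k] <- xm[i, k] - h
    g[i, k] <- -(energy_fn(xp) - energy_fn(xm)) / (2 * h)
  }
  g
}
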