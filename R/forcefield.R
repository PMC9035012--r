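#' Minimal force field for exercising the dynamics engine
#'
#' Harmonic bonds and angles, cosine torsions, Lennard-Jones and Coulomb
#' non-bonded terms with a plain cutoff, and an optional implicit-solvation
#' handle. This is a self-contained toy parameterisation so the stochastic
#' dynamics machinery runs without external topology/parameter files; it is
#' not a calibrated biomolecular force field.
#'
#' @param bonds data.frame(i, j, b0, kb): b0 nm, kb kJ mol^-1 nm^-2
#' @param angles data.frame(i, j, k, theta0, ktheta): theta0 degrees (j is
#'   the vertex), ktheta kJ mol^-1 rad^-2
#' @param torsions data.frame(i, j, k, l, mult, phase, kphi): phase degrees,
#'   kphi kJ/mol; V = kphi (1 + cos(mult * phi - phase))
#' @param lj data.frame(c6, c12) per atom (kJ mol^-1 nm^6 / nm^12),
#'   combined by geometric mean; NULL disables LJ
#' @param charges per-atom charges (e); NULL disables electrostatics
#' @param eps_r relative dielectric permittivity
#' @param cutoff non-bonded cutoff in nm
#' @param sasa optional list(params=[sasa_params()], ...) enabling the
#'   implicit-solvation term
#' @return object of class `"toy_forcefield"`
#' @export
toy_forcefield <- function(bonds = NULL, angles = NULL, torsions = NULL,
                           lj = NULL, charges = NULL, eps_r = 1,
                           cutoff = 1.4, sasa = NULL) {
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 lj = lj, charges = charges, eps_r = eps_r,
                 cutoff = cutoff, sasa = sasa),
            class = "toy_forcefield")
}

# Coulomb conversion factor, kJ mol^-1 nm e^-2
.f_elec <- 138.935458

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Evaluate the toy force field
#'
#' @param xyz n x 3 coordinates (nm)
#' @param ff a [toy_forcefield()]
#' @param top topology (needed for non-bonded exclusions and the
#'   implicit-solvation term)
#' @return list with named per-term energies `terms` (kJ/mol), total
#'   `energy`, and `forces` (n x 3, kJ mol^-1 nm^-1)
#' @export
ff_eval <- function(xyz, ff, top = NULL) {
  xyz <- as_xyz(xyz)
  n <- nrow(xyz)
  forces <- matrix(0, n, 3)
  terms <- c(bond = 0, angle = 0, torsion = 0, lj = 0, coulomb = 0, sasa = 0)

  if (!is.null(ff$bonds) && nrow(ff$bonds) > 0) {
    b <- ff$bonds
    d <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    terms["bond"] <- sum(0.5 * b$kb * (r - b$b0)^2)
    fmag <- -b$kb * (r - b$b0) / r        # dV/dr along unit vector
    fv <- fmag * d
    forces <- acc_forces(forces, b$i, fv)
    forces <- acc_forces(forces, b$j, -fv)
  }

  if (!is.null(ff$angles) && nrow(ff$angles) > 0) {
    a <- ff$angles
    v1 <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    v2 <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    ct <- rowSums(v1 * v2) / (n1 * n2)
    ct <- pmin(1, pmax(-1, ct))
    th <- acos(ct)
    st <- sqrt(pmax(1e-12, 1 - ct^2))
    th0 <- a$theta0 * pi / 180
    terms["angle"] <- sum(0.5 * a$ktheta * (th - th0)^2)
    dVdth <- a$ktheta * (th - th0)
    # d(theta)/dr via d(cos theta)
    dci <- (v2 / n2 - ct * v1 / n1) / n1
    dck <- (v1 / n1 - ct * v2 / n2) / n2
    fi <- (dVdth / st) * dci
    fk <- (dVdth / st) * dck
    forces <- acc_forces(forces, a$i, fi)
    forces <- acc_forces(forces, a$k, fk)
    forces <- acc_forces(forces, a$j, -(fi + fk))
  }

  if (!is.null(ff$torsions) && nrow(ff$torsions) > 0) {
    t <- ff$torsions
    b1 <- xyz[t$j, , drop = FALSE] - xyz[t$i, , drop = FALSE]
    b2 <- xyz[t$k, , drop = FALSE] - xyz[t$j, , drop = FALSE]
    b3 <- xyz[t$l, , drop = FALSE] - xyz[t$k, , drop = FALSE]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
    b2n <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(cross3(n1, n2) * b2) / b2n, rowSums(n1 * n2))
    delta <- t$phase * pi / 180
    terms["torsion"] <- sum(t$kphi * (1 + cos(t$mult * phi - delta)))
    dVdphi <- -t$kphi * t$mult * sin(t$mult * phi - delta)
    dpi_ <- -(b2n / n1sq) * n1
    dpl <- (b2n / n2sq) * n2
    s12 <- rowSums(b1 * b2) / b2n^2
    s32 <- rowSums(b3 * b2) / b2n^2
    dpj <- (-s12 - 1) * dpi_ + s32 * dpl
    dpk <- (-s32 - 1) * dpl + s12 * dpi_
    forces <- acc_forces(forces, t$i, -dVdphi * dpi_)
    forces <- acc_forces(forces, t$j, -dVdphi * dpj)
    forces <- acc_forces(forces, t$k, -dVdphi * dpk)
    forces <- acc_forces(forces, t$l, -dVdphi * dpl)
  }

  if ((!is.null(ff$lj) || !is.null(ff$charges)) && n > 1) {
    excl <- nonbonded_exclusions(top, n)
    d <- as.matrix(stats::dist(xyz))
    sel <- which(upper.tri(d) & d < ff$cutoff & !excl, arr.ind = TRUE)
    if (nrow(sel) > 0) {
      i1 <- sel[, 1]; i2 <- sel[, 2]
      r <- d[sel]
      if (any(r <= 1e-9)) stop("overlapping non-bonded atoms at zero distance")
      u <- (xyz[i1, , drop = FALSE] - xyz[i2, , drop = FALSE]) / r
      fmag <- numeric(length(r))
      if (!is.null(ff$lj)) {
        c6 <- sqrt(ff$lj$c6[i1] * ff$lj$c6[i2])
        c12 <- sqrt(ff$lj$c12[i1] * ff$lj$c12[i2])
        terms["lj"] <- sum(c12 / r^12 - c6 / r^6)
        fmag <- fmag + (12 * c12 / r^13 - 6 * c6 / r^7)
      }
      if (!is.null(ff$charges)) {
        qq <- .f_elec * ff$charges[i1] * ff$charges[i2] / ff$eps_r
        terms["coulomb"] <- sum(qq / r)
        fmag <- fmag + qq / r^2
      }
      fv <- fmag * u
      forces <- acc_forces(forces, i1, fv)
      forces <- acc_forces(forces, i2, -fv)
    }
  }

  if (!is.null(ff$sasa)) {
    if (is.null(top)) stop("the implicit-solvation term needs a topology")
    sa <- do.call(sasa_energy_forces,
                  c(list(xyz = xyz, top = top), ff$sasa))
    terms["sasa"] <- sa$energy
    forces <- forces + sa$forces
  }

  list(terms = terms, energy = sum(terms), forces = forces)
}

# accumulate rows of f into forces[idx, ] allowing duplicated indices
acc_forces <- function(forces, idx, f) {
  agg <- rowsum(f, group = idx)
  w <- as.integer(rownames(agg))
  forces[w, ] <- forces[w, ] + agg
  forces
}

# logical n x n matrix of excluded non-bonded pairs (first + second covalent
# neighbours)
nonbonded_exclusions <- function(top, n) {
  excl <- matrix(FALSE, n, n)
  if (is.null(top) || nrow(top$bonds) == 0) return(excl)
  adjm <- matrix(FALSE, n, n)
  adjm[top$bonds] <- TRUE
  adjm <- adjm | t(adjm)
  second <- (adjm %*% adjm) > 0
  excl <- adjm | second
  diag(excl) <- FALSE
  excl
}
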