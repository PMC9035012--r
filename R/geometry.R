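#' Radius of gyration
#'
#' Mass-weighted rms distance of the atoms from their mass-weighted centre:
#' `sqrt(sum(m_i (r_i - r_cm)^2) / M)`. The unnormalised raw-sum variant
#' (no division by the total mass) and unweighted sums are available behind
#' flags.
#'
#' @param xyz n x 3 coordinates (nm)
#' @param top topology (or numeric mass vector)
#' @param mass_weighted weight the squared deviations by atomic mass
#' @param normalise divide by the total weight (TRUE for the standard
#'   definition)
#' @return radius of gyration in nm
#' @export
radius_of_gyration <- function(xyz, top, mass_weighted = TRUE,
                               normalise = TRUE) {
  xyz <- as_xyz(xyz)
  m <- if (is.numeric(top)) top else top$atoms$mass
  if (sum(m) <= 0) stop("total mass is zero")
  cm <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, cm)^2)
  w <- if (mass_weighted) m else rep(1, length(m))
  s <- sum(w * d2)
  if (normalise) s <- s / sum(w)
  sqrt(s)
}

#' Hydrogen-bond geometric criterion
#'
#' @param max_ha_nm maximum hydrogen-acceptor distance (strict <), nm
#' @param min_dha_deg minimum donor-hydrogen-acceptor angle (strict >), deg
#' @return list criterion object
#' @export
hbond_criterion <- function(max_ha_nm = 0.25, min_dha_deg = 135) {
  stopifnot(max_ha_nm > 0, min_dha_deg > 0, min_dha_deg < 180)
  list(max_ha_nm = max_ha_nm, min_dha_deg = min_dha_deg)
}

# donor/acceptor derivation: acceptors are N/O atoms; donors are H atoms
# covalently bound to an N or O
hbond_sites <- function(top) {
  elem <- top$atoms$element
  acceptors <- which(elem %in% c("N", "O"))
  donors <- data.frame(d = integer(0), h = integer(0))
  if (nrow(top$bonds) > 0) {
    for (r in seq_len(nrow(top$bonds))) {
      a <- top$bonds[r, 1]; b <- top$bonds[r, 2]
      if (elem[a] == "H" && elem[b] %in% c("N", "O"))
        donors <- rbind(donors, data.frame(d = b, h = a))
      if (elem[b] == "H" && elem[a] %in% c("N", "O"))
        donors <- rbind(donors, data.frame(d = a, h = b))
    }
  }
  list(acceptors = acceptors, donors = donors)
}

#' Hydrogen-bond detection
#'
#' A hydrogen bond exists when the hydrogen-acceptor distance is strictly
#' below 0.25 nm and the donor-hydrogen-acceptor angle strictly above 135
#' degrees. Donors are N/O atoms with a covalently bound hydrogen, acceptors
#' any N/O atom. On a trajectory, per-pair occupancies over the frames are
#' reported.
#'
#' @param x an n x 3 conformation or a [trajectory()]
#' @param top topology
#' @param criterion a [hbond_criterion()]
#' @return data.frame(donor, hydrogen, acceptor, occupancy) — occupancy is
#'   1 for a single conformation; empty (zero rows) when no donors or
#'   acceptors exist
#' @export
hydrogen_bonds <- function(x, top, criterion = hbond_criterion()) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(as_xyz(x))
  sites <- hbond_sites(top)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), occupancy = numeric(0))
  if (nrow(sites$donors) == 0 || length(sites$acceptors) == 0) return(empty)
  counts <- new.env(parent = emptyenv())
  for (fr in frames) {
    for (r in seq_len(nrow(sites$donors))) {
      d <- sites$donors$d[r]; h <- sites$donors$h[r]
      for (a in sites$acceptors) {
        if (a == d) next
        rha <- fr[a, ] - fr[h, ]
        dist_ha <- sqrt(sum(rha^2))
        if (dist_ha >= criterion$max_ha_nm) next
        rhd <- fr[d, ] - fr[h, ]
        ct <- sum(rha * rhd) / (dist_ha * sqrt(sum(rhd^2)))
        ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
        if (ang > criterion$min_dha_deg) {
          key <- paste(d, h, a, sep = "_")
          counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) return(empty)
  parts <- do.call(rbind, strsplit(keys, "_"))
  out <- data.frame(donor = as.integer(parts[, 1]),
                    hydrogen = as.integer(parts[, 2]),
                    acceptor = as.integer(parts[, 3]),
                    occupancy = vapply(keys, function(k) counts[[k]],
                                       numeric(1)) / length(frames))
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Hydrogen-bonding extent relative to a reference structure
#'
#' Number of hydrogen bonds weighted by their fractional occurrence,
#' divided by the hydrogen-bond count of a reference structure, as a
#' percentage.
#'
#' @param bonds data.frame from [hydrogen_bonds()] (occupancy column)
#' @param n_reference hydrogen-bond count of the reference structure
#' @return percentage (100 = same extent as the reference)
#' @export
hbond_extent <- function(bonds, n_reference) {
  stopifnot(n_reference > 0)
  100 * sum(bonds$occupancy) / n_reference
}

#' Torsion (dihedral) angle
#'
#' @param xyz n x 3 coordinates (nm)
#' @param idx four atom indices i-j-k-l
#' @return dihedral angle in degrees, in (-180, 180]
#' @export
torsion_angle <- function(xyz, idx) {
  xyz <- as_xyz(xyz)
  stopifnot(length(idx) == 4)
  b1 <- xyz[idx[2], ] - xyz[idx[1], ]
  b2 <- xyz[idx[3], ] - xyz[idx[2], ]
  b3 <- xyz[idx[4], ] - xyz[idx[3], ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear atoms in torsion")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Torsion-angle time series for autocorrelation analysis
#'
#' Represents each frame's torsion as the unit vector (cos chi, sin chi) so
#' the autocorrelation dot product is periodicity-safe; the raw angle in
#' degrees is available via `embed = "angle"`.
#'
#' @param traj a [trajectory()]
#' @param idx four atom indices
#' @param embed `"unit-circle"` (default) or `"angle"`
#' @return a [time_series()]: matrix of (cos, sin) rows (or a single angle
#'   column) at the trajectory's sampling interval
#' @export
torsion_series <- function(traj, idx, embed = c("unit-circle", "angle")) {
  embed <- match.arg(embed)
  ang <- vapply(traj$frames, torsion_angle, numeric(1), idx = idx)
  dt <- if (length(traj$times) > 1) diff(traj$times)[1] else 1
  values <- if (embed == "unit-circle")
    cbind(cos(ang * pi / 180), sin(ang * pi / 180))
  else matrix(ang, ncol = 1)
  time_series(values, dt)
}
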