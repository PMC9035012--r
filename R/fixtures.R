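#' Ideal internal-coordinate table for fixtures
#' @return named numeric vector of bond lengths (nm) and angles (deg)
#' @export
ideal_geometry <- function() {
  path <- system.file("extdata", "ideal_geometry.tsv", package = "implisolv")
  if (path == "") path <- file.path("inst", "extdata", "ideal_geometry.tsv")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$parameter)
}

# natural-extension placement: position D bonded to C with |C-D| = d,
# angle B-C-D = theta (deg), dihedral A-B-C-D = phi (deg). Exact in the
# bond length, so generated bonds equal their constraint targets.
place_atom <- function(A, B, C, d, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-d * cos(th), d * sin(th) * cos(ph), d * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Toy peptide-like chain
#'
#' Deterministic backbone (N, CA, C, O) plus a methyl CB per residue with
#' ideal geometry, SASA type codes, a full bond list and bond-length
#' constraints whose targets the generated coordinates satisfy exactly.
#' An extended-strand conformation (phi = -135, psi = 135, omega = 180).
#'
#' @param n_residues number of residues (>= 1)
#' @param seed RNG seed (used only when `jitter > 0`)
#' @param jitter optional Gaussian coordinate noise (nm; default 0 keeps
#'   the constraints exact)
#' @return list with `top` (topology) and `xyz` (n x 3 conformation, nm)
#' @export
make_toy_chain <- function(n_residues, seed = 1, jitter = 0) {
  stopifnot(n_residues >= 1)
  g <- ideal_geometry()
  phi <- -135; psi <- 135; omega <- 180
  atoms <- list(); coords <- list(); bonds <- list()
  add <- function(name, type, resid, at) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = name, sasa_type = type, resid = resid, resname = "TOY",
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- at
    length(atoms)
  }
  bond <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)

  iN <- add("N", "N", 1, c(0, 0, 0))
  iCA <- add("CA", "CH1", 1, c(g["bond_N_CA"], 0, 0))
  aNCAC <- g["angle_N_CA_C"] * pi / 180
  iC <- add("C", "C", 1,
            coords[[iCA]] + g["bond_CA_C"] *
              c(-cos(aNCAC), sin(aNCAC), 0))
  bond(iN, iCA); bond(iCA, iC)
  for (r in seq_len(n_residues)) {
    iCB <- add("CB", "CH3", r,
               place_atom(coords[[iC]], coords[[iN]], coords[[iCA]],
                          g["bond_CA_CB"], g["angle_backbone_CB"], -122))
    bond(iCA, iCB)
    if (r < n_residues) {
      iNn <- add("N", "N", r + 1,
                 place_atom(coords[[iN]], coords[[iCA]], coords[[iC]],
                            g["bond_C_N"], g["angle_CA_C_N"], psi))
      iO <- add("O", "O", r,
                place_atom(coords[[iN]], coords[[iCA]], coords[[iC]],
                           g["bond_C_O"], g["angle_CA_C_O"], psi + 180))
      bond(iC, iO); bond(iC, iNn)
      iCAn <- add("CA", "CH1", r + 1,
                  place_atom(coords[[iCA]], coords[[iC]], coords[[iNn]],
                             g["bond_N_CA"], g["angle_C_N_CA"], omega))
      bond(iNn, iCAn)
      iCn <- add("C", "C", r + 1,
                 place_atom(coords[[iC]], coords[[iNn]], coords[[iCAn]],
                            g["bond_CA_C"], g["angle_N_CA_C"], phi))
      bond(iCAn, iCn)
      iN <- iNn; iCA <- iCAn; iC <- iCn
    } else {
      iO <- add("O", "O", r,
                place_atom(coords[[iN]], coords[[iCA]], coords[[iC]],
                           g["bond_C_O"], g["angle_CA_C_O"], psi + 180))
      bond(iC, iO)
    }
  }
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  bonds <- do.call(rbind, bonds)
  if (jitter > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter),
                        nrow(xyz), 3)
  }
  d <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                       xyz[bonds[, 2], , drop = FALSE])^2))
  constraints <- data.frame(i = bonds[, 1], j = bonds[, 2], length_nm = d)
  list(top = topology(atoms, bonds, constraints), xyz = unname(xyz))
}

#' Unit bond vector diffusing uniformly in a cone
#'
#' Orientations are drawn uniformly on the spherical cap of the given
#' half-angle about +z (cos(polar angle) uniform on [cos(beta), 1]); the
#' closed-form order parameter is [cone_order_parameter()].
#'
#' @param half_angle_deg cone half-angle, 0 < beta < 90
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param bond_length fixed bond length (nm)
#' @return list with `top` (2-atom topology) and `traj`
#' @export
make_cone_trajectory <- function(half_angle_deg, n_frames, seed = 1,
                                 bond_length = 0.1) {
  stopifnot(half_angle_deg > 0, half_angle_deg < 90, n_frames >= 2)
  set.seed(seed)
  ct <- stats::runif(n_frames, cos(half_angle_deg * pi / 180), 1)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n_frames, 0, 2 * pi)
  u <- cbind(st * cos(ph), st * sin(ph), ct)
  atoms <- data.frame(name = c("N", "HN"), sasa_type = c("N", "H"),
                      resid = 1, resname = "FIX",
                      stringsAsFactors = FALSE)
  top <- topology(atoms, matrix(c(1L, 2L), ncol = 2),
                  data.frame(i = 1L, j = 2L, length_nm = bond_length))
  frames <- lapply(seq_len(n_frames), function(f)
    rbind(c(0, 0, 0), bond_length * u[f, ]))
  list(top = top, traj = trajectory(frames, seq_len(n_frames) - 1))
}

#' NOE restraint fixture with planted violations
#'
#' Draws restraints between the proton sites of a conformation and sets
#' the upper bounds so that the first restraints violate by exactly the
#' requested sizes (after pseudo-atom corrections) and the rest are
#' satisfied with random slack. Returns the ground-truth histogram for the
#' generating conformation.
#'
#' @param top topology
#' @param xyz generating conformation (nm)
#' @param n_restraints total number of restraints
#' @param violations numeric vector of planted violation sizes (nm);
#'   must be no longer than `n_restraints`
#' @param seed RNG seed
#' @param wildcard_frac fraction of records written with a wildcard spec
#'   on a methyl site
#' @return list with `restraints` (NOE table), `expected_histogram`, and
#'   `expected_violations`
#' @export
make_noe_fixture <- function(top, xyz, n_restraints, violations = numeric(0),
                             seed = 1, wildcard_frac = 0.2) {
  stopifnot(length(violations) <= n_restraints)
  set.seed(seed)
  vh <- build_virtual_hydrogens(xyz, top)
  pool <- vh$sites[vh$sites$kind %in% c("CH1", "CH3", "polar", "CR1"), ]
  if (nrow(pool) < 2) stop("topology provides too few proton sites")
  recs <- list()
  for (k in seq_len(n_restraints)) {
    pick <- sample(nrow(pool), 2)
    nm <- pool$name[pick]
    wc <- stats::runif(2) < wildcard_frac & pool$kind[pick] == "CH3"
    nm[wc] <- paste0(nm[wc], "*")
    recs[[k]] <- data.frame(
      resid_i = pool$resid[pick[1]], atom_i = nm[1],
      resid_j = pool$resid[pick[2]], atom_j = nm[2],
      bound_nm = NA_real_, stringsAsFactors = FALSE)
  }
  restraints <- do.call(rbind, recs)
  dc <- calc_noe_distances(xyz, top, restraints)
  nv <- length(violations)
  bound <- dc$d_calc - dc$correction_nm
  if (nv > 0) bound[seq_len(nv)] <- bound[seq_len(nv)] - violations
  if (nv < n_restraints) {
    rest <- (nv + 1):n_restraints
    bound[rest] <- bound[rest] + stats::runif(length(rest), 0.05, 0.2)
  }
  if (any(bound <= 0))
    stop("planted violations too large for the generating geometry")
  restraints$bound_nm <- bound
  list(restraints = restraints,
       expected_histogram = deviation_histogram_counts(
         violations, .deviation_spec$noe$edges),
       expected_violations = violations)
}

#' Synthetic experimental J-coupling and S2 tables
#'
#' Back-calculates backbone couplings and CA-CB bond-vector order
#' parameters from a truth trajectory (or conformation), adds Gaussian
#' noise, and flags a stated fraction of coupling records as
#' stereospecifically unassigned pairs (their experimental values may be
#' stored swapped) and another fraction as capped at the Karplus maximum,
#' so the assignment-resolution and capping code paths are exercised.
#'
#' @param x truth [trajectory()] or conformation
#' @param top topology
#' @param noise_j Gaussian noise on couplings (Hz)
#' @param noise_s2 Gaussian noise on S2
#' @param seed RNG seed
#' @param unassigned_frac fraction of coupling records grouped into
#'   unassigned pairs
#' @param cap_frac fraction of coupling records flagged as capped
#' @return list with `j` and `s2` tables plus `truth` values
#' @export
make_exp_tables <- function(x, top, noise_j = 0, noise_s2 = 0, seed = 1,
                            unassigned_frac = 0.2, cap_frac = 0.1) {
  stopifnot(noise_j >= 0, noise_s2 >= 0)
  set.seed(seed)
  resids <- sort(unique(top$atoms$resid))
  jres <- resids[resids > min(resids)]   # first residue lacks an amide H
  jrec <- data.frame(resid = jres, type = "backbone",
                     stringsAsFactors = FALSE)
  jc <- calc_j_couplings(x, top, jrec)
  truth_j <- jc$calc_hz
  exp_j <- truth_j + stats::rnorm(length(truth_j), sd = noise_j)
  group <- rep(NA_integer_, length(jres))
  npair <- floor(unassigned_frac * length(jres) / 2)
  swapped <- logical(length(jres))
  if (npair > 0) {
    for (p in seq_len(npair)) {
      rows <- c(2 * p - 1, 2 * p)
      group[rows] <- p
      if (stats::runif(1) < 0.5) {
        exp_j[rows] <- exp_j[rev(rows)]
        swapped[rows] <- TRUE
      }
    }
  }
  jmax <- karplus_extrema(karplus_params("backbone"))["max"]
  cap_flag <- stats::runif(length(jres)) < cap_frac
  exp_j[cap_flag] <- pmin(exp_j[cap_flag], jmax)
  jtab <- data.frame(resid = jres, type = "backbone", value_hz = exp_j,
                     group = group, cap_flag = cap_flag,
                     stringsAsFactors = FALSE)

  traj <- if (inherits(x, "trajectory")) x else
    trajectory(list(as_xyz(x), as_xyz(x)), c(0, 1))
  s2rec <- lapply(resids, function(rr) {
    ca <- which(top$atoms$resid == rr & top$atoms$name == "CA")
    cb <- which(top$atoms$resid == rr & top$atoms$name == "CB")
    if (length(ca) != 1 || length(cb) != 1) return(NULL)
    data.frame(resid = rr, atom_a = "CB", atom_b = "CA",
               value = order_parameter(traj, cb, ca),
               stringsAsFactors = FALSE)
  })
  s2tab <- do.call(rbind, s2rec)
  truth_s2 <- s2tab$value
  s2tab$value <- truth_s2 + stats::rnorm(length(truth_s2), sd = noise_s2)
  list(j = jtab, s2 = s2tab,
       truth = list(j = truth_j, s2 = truth_s2, swapped = swapped))
}
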