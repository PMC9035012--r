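#' Covalent neighbour order from the bond graph
#'
#' Classifies atom pairs as first covalent neighbours (bonded), second
#' neighbours (two bonds apart) or unrelated, by breadth-first search on the
#' bond graph. Pairs three or more bonds apart count as unrelated and take
#' the full pair factor 1 in the area product.
#'
#' @param top a topology
#' @return function `(i, k) -> p_ij` mapping vectors of 1-based atom index
#'   pairs to pair reduction factors, given `p_first`/`p_next`
#' @keywords internal
neighbour_order_map <- function(top) {
  n <- n_atoms(top)
  adj <- vector("list", n)
  if (nrow(top$bonds) > 0) {
    for (r in seq_len(nrow(top$bonds))) {
      a <- top$bonds[r, 1]; b <- top$bonds[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  first <- new.env(parent = emptyenv())
  second <- new.env(parent = emptyenv())
  key <- function(i, k) paste0(pmin(i, k), "_", pmax(i, k))
  for (a in seq_len(n)) {
    for (b in adj[[a]]) if (b > a) assign(key(a, b), TRUE, envir = first)
    nb <- adj[[a]]
    if (length(nb) > 1) {
      cmb <- utils::combn(sort(unique(nb)), 2)
      for (c_i in seq_len(ncol(cmb)))
        assign(key(cmb[1, c_i], cmb[2, c_i]), TRUE, envir = second)
    }
  }
  function(i, k, p_first, p_next) {
    ks <- key(i, k)
    out <- rep(1, length(ks))
    is1 <- vapply(ks, exists, logical(1), envir = first)
    is2 <- !is1 & vapply(ks, exists, logical(1), envir = second)
    out[is1] <- p_first
    out[is2] <- p_next
    out
  }
}

# shared machinery for areas / energy / forces
sasa_eval <- function(xyz, top, params, want_forces = TRUE,
                      hydrogens_occlude = TRUE,
                      allow_undefined_sigma = FALSE) {
  xyz <- as_xyz(xyz)
  n <- n_atoms(top)
  if (nrow(xyz) != n) stop("coordinate/atom count mismatch")
  type <- top$atoms$sasa_type
  R <- unname(params$R[type])
  p <- unname(params$p[type])
  sigma <- unname(params$sigma[type])

  excluded <- is.na(R)
  if (!hydrogens_occlude) excluded <- excluded | top$atoms$element == "H"
  undef_sigma <- !excluded & is.na(sigma)
  if (any(undef_sigma)) {
    if (!allow_undefined_sigma)
      stop("sigma undefined for atom type(s) in the '", params$set_id,
           "' set: ", paste(unique(type[undef_sigma]), collapse = ", "),
           " (set allow_undefined_sigma = TRUE to treat them as occluders",
           " with zero solvation weight)")
    sigma[undef_sigma] <- 0
  }
  act <- which(!excluded)
  S <- rep(NA_real_, n)
  S[act] <- 4 * pi * (R[act] + params$R_solv)^2

  # directed pair list among active atoms within the contact cutoff
  na <- length(act)
  ii <- kk <- integer(0); rr <- numeric(0)
  if (na > 1) {
    xa <- xyz[act, , drop = FALSE]
    d <- as.matrix(stats::dist(xa))
    cut <- outer(R[act], R[act], `+`) + 2 * params$R_solv
    sel <- which(d < cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(sel) > 0) {
      if (any(d[sel] <= 0)) stop("coincident atoms at zero distance")
      i1 <- act[sel[, 1]]; i2 <- act[sel[, 2]]
      # both directions: occlusion of i by k and of k by i
      ii <- c(i1, i2); kk <- c(i2, i1)
      rr <- c(d[sel], d[sel])
    }
  }

  area <- S
  clamped <- rep(FALSE, n)
  forces <- matrix(0, n, 3)
  npair <- length(ii)
  if (npair > 0) {
    pmap <- neighbour_order_map(top)
    ppair <- pmap(ii, kk, params$p_first, params$p_next)
    b <- pi * (R[ii] + params$R_solv) *
      (R[ii] + R[kk] + 2 * params$R_solv - rr) * (1 + (R[kk] - R[ii]) / rr)
    graw <- 1 - p[ii] * ppair * b / S[ii]
    f <- pmin(1, pmax(0, graw))
    is_clamped <- graw < 0 | graw > 1
    if (any(is_clamped)) clamped[unique(ii[is_clamped])] <- TRUE

    prod_i <- rep(1, n)
    pt <- tapply(f, ii, prod)
    prod_i[as.integer(names(pt))] <- pt
    area <- S * prod_i

    if (want_forces) {
      db <- overlap_reduction_deriv(rr, R[ii], R[kk], params$R_solv)
      dfdr <- -p[ii] * ppair * db / S[ii]
      dfdr[is_clamped] <- 0   # clamped factors are locally constant
      # product over i's factors excluding the (i,k) one
      P <- ifelse(f > 1e-12, prod_i[ii] / f, NA_real_)
      if (anyNA(P)) {
        idx_by_i <- split(seq_len(npair), ii)
        for (q in which(is.na(P))) {
          rows <- idx_by_i[[as.character(ii[q])]]
          P[q] <- prod(f[rows[rows != q]])
        }
      }
      s <- sigma[ii] * S[ii] * P * dfdr        # d(sigma_i A_i)/d r_ik
      u <- (xyz[ii, , drop = FALSE] - xyz[kk, , drop = FALSE]) / rr
      delta <- s * u
      nz <- s != 0
      if (any(nz)) {
        agg_i <- rowsum(delta[nz, , drop = FALSE], group = ii[nz])
        idx <- as.integer(rownames(agg_i))
        forces[idx, ] <- forces[idx, ] - agg_i
        agg_k <- rowsum(delta[nz, , drop = FALSE], group = kk[nz])
        idx <- as.integer(rownames(agg_k))
        forces[idx, ] <- forces[idx, ] + agg_k
      }
    }
  }
  energy <- sum(sigma[act] * area[act])
  list(area = area, S = S, energy = energy, forces = forces,
       clamped = clamped, excluded = which(excluded), sigma = sigma)
}

#' Approximate per-atom solvent-accessible areas
#'
#' Evaluates the multiplicative overlap-reduction approximation: each atom's
#' isolated probe-accessible area is reduced by one factor per occluding
#' neighbour, with pair factors distinguishing first and second covalent
#' neighbours. Factors are clamped to \[0, 1\] at unphysically short
#' distances (flagged in the result); atoms with undefined radii (OW, CH4,
#' DUM) are excluded from both area and occlusion and reported as NA.
#'
#' @param xyz n x 3 coordinates (nm)
#' @param top topology
#' @param params [sasa_params()]
#' @param hydrogens_occlude should H atoms occlude neighbours (default TRUE;
#'   they never contribute energy, their sigma being zero)
#' @return numeric vector of per-atom areas (nm^2; NA for excluded atoms)
#' @export
atomic_areas <- function(xyz, top, params = sasa_params(),
                         hydrogens_occlude = TRUE) {
  sasa_eval(xyz, top, params, want_forces = FALSE,
            hydrogens_occlude = hydrogens_occlude,
            allow_undefined_sigma = TRUE)$area
}

#' Implicit-solvation energy and analytical forces
#'
#' The solvation energy is the sigma-weighted sum of the approximate
#' accessible areas; forces are its exact analytical gradient (product rule
#' over the per-atom occlusion factors). The net force and net torque vanish
#' by construction (the energy depends on interatomic distances only).
#'
#' @inheritParams atomic_areas
#' @param allow_undefined_sigma treat types with undefined sigma but defined
#'   radius (OE, CH0, CH2r in the per-type set) as occluders with zero
#'   weight instead of raising
#' @return object of class `"sasa_result"`: per-atom `area` and isolated
#'   area `S` (nm^2), total `energy` (kJ/mol), `forces` (n x 3,
#'   kJ mol^-1 nm^-1), per-atom `clamped` flags, `excluded` atom indices,
#'   and `class_totals` (hydrophilic/hydrophobic/total areas, nm^2)
#' @export
sasa_energy_forces <- function(xyz, top, params = sasa_params(),
                               hydrogens_occlude = TRUE,
                               allow_undefined_sigma = FALSE) {
  res <- sasa_eval(xyz, top, params, want_forces = TRUE,
                   hydrogens_occlude = hydrogens_occlude,
                   allow_undefined_sigma = allow_undefined_sigma)
  out <- structure(res, class = "sasa_result")
  out$class_totals <- classify_areas(out, top, params)
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA result: energy %.4f kJ/mol over %d atoms (%d excluded)\n",
              x$energy, length(x$area), length(x$excluded)))
  ct <- x$class_totals
  cat(sprintf("  areas nm^2: hydrophilic %.3f, hydrophobic %.3f, total %.3f\n",
              ct["hydrophilic"], ct["hydrophobic"], ct["total"]))
  if (any(x$clamped))
    cat(sprintf("  note: %d atom(s) had clamped occlusion factors\n",
                sum(x$clamped)))
  invisible(x)
}

#' Class totals of accessible area
#'
#' Sums per-atom areas into hydrophilic (nitrogen/oxygen types), hydrophobic
#' (carbon types) and total (every atom with a defined area, including H and
#' S) accessible surface, in nm^2.
#'
#' @param result a `"sasa_result"` or a per-atom area vector
#' @param top topology
#' @param params [sasa_params()] supplying the class membership
#' @return named numeric vector `c(hydrophilic=, hydrophobic=, total=)`
#' @export
classify_areas <- function(result, top, params = sasa_params()) {
  area <- if (is.list(result)) result$area else result
  cls <- unname(params$surface_class[top$atoms$sasa_type])
  ok <- !is.na(area)
  c(hydrophilic = sum(area[ok & cls == "hydrophilic"]),
    hydrophobic = sum(area[ok & cls == "hydrophobic"]),
    total = sum(area[ok]))
}
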