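#' Karplus parameter sets
#'
#' Coefficients of `J(theta) = a cos^2(theta) + b cos(theta) + c` relating a
#' three-bond scalar coupling to its intervening dihedral angle. The
#' `"backbone"` set (a = 6.4, b = -1.4, c = 1.9 Hz) applies to 3J(HN-HA),
#' the `"sidechain"` set (a = 9.5, b = -1.6, c = 1.8 Hz) to 3J(HA-HB).
#'
#' @param type `"backbone"` or `"sidechain"`
#' @return object of class `"karplus_params"` with fields a, b, c (Hz)
#' @export
karplus_params <- function(type = c("backbone", "sidechain")) {
  type <- match.arg(type)
  p <- switch(type,
              backbone = list(a = 6.4, b = -1.4, c = 1.9),
              sidechain = list(a = 9.5, b = -1.6, c = 1.8))
  p$type <- type
  stopifnot(abs(p$b) < p$a)
  structure(p, class = "karplus_params")
}

#' Karplus relation
#'
#' @param theta dihedral angle(s) in degrees
#' @param params a [karplus_params()] object (or list with a, b, c in Hz)
#' @return coupling(s) in Hz
#' @export
karplus_j <- function(theta, params = karplus_params("backbone")) {
  ct <- cos(theta * pi / 180)
  params$a * ct^2 + params$b * ct + params$c
}

#' Analytic extrema of a Karplus curve
#'
#' The quadratic in cos(theta) is minimised/maximised over cos in \[-1, 1\]:
#' candidates are the endpoints and the vertex -b/(2a) when interior.
#'
#' @param params a [karplus_params()] object
#' @return named vector c(min =, max =) in Hz
#' @export
karplus_extrema <- function(params) {
  f <- function(ct) params$a * ct^2 + params$b * ct + params$c
  cand <- c(-1, 1)
  v <- -params$b / (2 * params$a)
  if (v > -1 && v < 1) cand <- c(cand, v)
  vals <- f(cand)
  c(min = min(vals), max = max(vals))
}

#' Back-calculate 3J couplings from structures
#'
#' For each record, the coupling dihedral is measured directly on the
#' (virtual) hydrogen positions — H-N-CA-HA for backbone records,
#' HA-CA-CB-HB for side-chain records — frame by frame; the per-frame
#' Karplus couplings are arithmetically averaged over the trajectory.
#'
#' @param x a conformation (n x 3) or a [trajectory()]
#' @param top topology
#' @param records data.frame with columns `resid` and `type`
#'   ("backbone"/"sidechain"); a `beta_proton` column may name which HB
#'   proton to use for side chains (default "HB2")
#' @return data.frame: the records plus `calc_hz` (NA where atoms could not
#'   be resolved) and `resolved`
#' @export
calc_j_couplings <- function(x, top, records) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(as_xyz(x))
  nr <- nrow(records)
  acc <- matrix(NA_real_, length(frames), nr)
  bp <- if (!is.null(records$beta_proton)) records$beta_proton else
    rep("HB2", nr)
  for (f in seq_along(frames)) {
    vh <- build_virtual_hydrogens(frames[[f]], top)
    axyz <- vh$xyz
    for (r in seq_len(nr)) {
      rid <- records$resid[r]
      at <- function(nm) {
        hit <- which(top$atoms$resid == rid & top$atoms$name == nm)
        if (length(hit) == 1) return(hit)
        hit <- which(vh$sites$resid == rid & vh$sites$name == nm)
        if (length(hit) == 1) return(vh$sites$index[hit])
        NA_integer_
      }
      idx <- if (records$type[r] == "backbone")
        c(at("HN"), at("N"), at("CA"), at("HA"))
      else
        c(at("HA"), at("CA"), at("CB"), at(bp[r]))
      if (anyNA(idx)) next
      th <- torsion_angle(axyz, idx)
      pars <- karplus_params(records$type[r])
      acc[f, r] <- karplus_j(th, pars)
    }
  }
  records$calc_hz <- colMeans(acc)
  records$resolved <- !is.na(records$calc_hz)
  records
}

#' Resolve stereospecifically unassigned value pairs
#'
#' Given calculated and experimental value pairs whose assignment to the two
#' sites is unknown, chooses the pairing that minimises the summed absolute
#' deviation; exact ties keep the input order. The optimal pairing never
#' has larger total deviation than either fixed pairing.
#'
#' @param calc length-2 numeric vector (or n x 2 matrix) of calculated
#'   values in site order
#' @param exp_vals length-2 numeric vector (or n x 2 matrix) of
#'   experimental values in reported order
#' @return list with `exp_assigned` (experimental values reordered onto the
#'   calculated sites), `deviations` (|calc - exp_assigned|), and `swapped`
#' @export
resolve_ambiguous_assignment <- function(calc, exp_vals) {
  cm <- if (is.null(dim(calc))) matrix(calc, ncol = 2) else as.matrix(calc)
  em <- if (is.null(dim(exp_vals))) matrix(exp_vals, ncol = 2) else
    as.matrix(exp_vals)
  if (ncol(cm) != 2 || ncol(em) != 2 || nrow(cm) != nrow(em))
    stop("unassigned records must come as value pairs")
  keep <- abs(cm[, 1] - em[, 1]) + abs(cm[, 2] - em[, 2])
  swap <- abs(cm[, 1] - em[, 2]) + abs(cm[, 2] - em[, 1])
  swapped <- swap < keep        # ties keep input order
  ea <- em
  ea[swapped, ] <- em[swapped, c(2, 1), drop = FALSE]
  list(exp_assigned = ea, deviations = abs(cm - ea), swapped = swapped)
}
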