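#' Least-squares rigid-body superposition
#'
#' Optimal proper rotation (SVD-based, reflections excluded) and translation
#' mapping the mobile structure onto the reference, fitted over a selection
#' of atoms. The returned coordinates apply the fit to all atoms.
#'
#' @param ref reference n x 3 coordinates (nm)
#' @param mobile mobile n x 3 coordinates (nm)
#' @param sel integer indices of the atoms used in the fit (default: all);
#'   must contain at least 3 non-collinear atoms
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (nm, over the fit selection), `sel`, and `fitted` (all-atom
#'   transformed mobile coordinates)
#' @export
superimpose <- function(ref, mobile, sel = NULL) {
  ref <- as_xyz(ref); mobile <- as_xyz(mobile)
  if (is.null(sel)) sel <- seq_len(nrow(ref))
  if (length(sel) < 3) stop("fit selection needs at least 3 atoms")
  A <- ref[sel, , drop = FALSE]
  B <- mobile[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2)
    stop("degenerate (collinear) fit selection")
  H <- crossprod(B0, A0)          # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # proper rotation: x_fit = R x + t
  tr <- ca - as.vector(R %*% cb)
  fitted <- t(R %*% t(mobile)) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted[sel, , drop = FALSE] - A)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, sel = sel,
       fitted = fitted)
}

#' Root-mean-square difference between two conformations
#'
#' @param a,b n x 3 coordinate matrices (nm)
#' @param sel atom subset over which to measure (default all)
#' @return RMSD in nm
#' @export
rmsd_value <- function(a, b, sel = NULL) {
  a <- as_xyz(a); b <- as_xyz(b)
  if (!is.null(sel)) {
    a <- a[sel, , drop = FALSE]; b <- b[sel, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is rigid-body superimposed onto the reference over `fit_sel`
#' before measuring the RMSD over `measure_sel`.
#'
#' @param traj a [trajectory()]
#' @param ref reference n x 3 coordinates (nm)
#' @param fit_sel atom indices for the superposition
#' @param measure_sel atom indices over which the RMSD is computed
#'   (default: the fit selection)
#' @return numeric vector, one RMSD (nm) per frame
#' @export
rmsd_series <- function(traj, ref, fit_sel = NULL, measure_sel = NULL) {
  ref <- as_xyz(ref)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(ref))
  if (is.null(measure_sel)) measure_sel <- fit_sel
  vapply(traj$frames, function(fr) {
    fit <- superimpose(ref, fr, fit_sel)
    rmsd_value(fit$fitted, ref, measure_sel)
  }, numeric(1))
}

#' Atom-positional root-mean-square fluctuations
#'
#' Each frame is superimposed onto the first frame over `fit_sel`; the RMSF
#' of each atom is the rms deviation from its trajectory-average position.
#'
#' @param traj a [trajectory()]
#' @param fit_sel atom indices used in the per-frame superposition
#' @return numeric vector of per-atom RMSF values (nm)
#' @export
rmsf <- function(traj, fit_sel = NULL) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  ref <- traj$frames[[1]]
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(ref))
  fitted <- lapply(traj$frames, function(fr)
    superimpose(ref, fr, fit_sel)$fitted)
  avg <- Reduce(`+`, fitted) / length(fitted)
  dev2 <- lapply(fitted, function(fr) rowSums((fr - avg)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}
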