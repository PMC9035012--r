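#' Generalised order parameter of a bond vector
#'
#' Ensemble-averaging estimator of S^2 for the vector from atom `a` to atom
#' `b`:
#' `S2 = 1/2 * (3 * sum_ab <mu_a mu_b / r^3>^2 - <1/r^3>^2) * r_eff^6`,
#' where mu are the direction cosines of the (superimposed) bond vector.
#' The average runs over non-overlapping time windows of the stated length
#' (a trailing partial window is discarded) and the per-window values are
#' averaged. With constrained bond lengths `r_eff` equals the constant bond
#' length; by default it is the mean observed length.
#'
#' The trajectory frames must already be superimposed on a common reference
#' (e.g. via [superimpose()] over the backbone) so overall rotation does
#' not contribute.
#'
#' @param traj a [trajectory()]
#' @param a,b atom indices defining the vector (a minus b)
#' @param window_ps averaging window length in ps (default: the whole
#'   trajectory as one window)
#' @param r_eff effective bond length in nm (default: mean observed)
#' @return S^2 in \[0, 1\]
#' @export
order_parameter <- function(traj, a, b, window_ps = NULL, r_eff = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("order parameter needs at least 2 frames")
  vec <- t(vapply(traj$frames, function(fr) fr[a, ] - fr[b, ], numeric(3)))
  r <- sqrt(rowSums(vec^2))
  mu <- vec / r
  if (is.null(r_eff)) r_eff <- mean(r)
  dtf <- if (length(traj$times) > 1) diff(traj$times)[1] else 1
  wlen <- if (is.null(window_ps)) nf else floor(window_ps / dtf)
  if (wlen > nf) stop("averaging window longer than the trajectory")
  wlen <- max(2, wlen)
  nwin <- floor(nf / wlen)
  s2w <- numeric(nwin)
  for (w in seq_len(nwin)) {
    sel <- ((w - 1) * wlen + 1):(w * wlen)
    invr3 <- r[sel]^-3
    m0 <- mean(invr3)
    ssum <- 0
    for (al in 1:3) for (be in 1:3)
      ssum <- ssum + mean(mu[sel, al] * mu[sel, be] * invr3)^2
    s2w[w] <- 0.5 * (3 * ssum - m0^2) * r_eff^6
  }
  mean(s2w)
}

#' Closed-form order parameter for uniform wobble in a cone
#'
#' `S = cos(beta) (1 + cos(beta)) / 2` for uniform orientation density on a
#' spherical cap of half-angle beta; returned squared.
#'
#' @param half_angle_deg cone half-angle in degrees
#' @return S^2
#' @export
cone_order_parameter <- function(half_angle_deg) {
  cb <- cos(half_angle_deg * pi / 180)
  (cb * (1 + cb) / 2)^2
}
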