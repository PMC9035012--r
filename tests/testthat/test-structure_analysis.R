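test_that("superposition recovers a planted rigid motion exactly", {
  ch <- make_toy_chain(5, seed = 1)
  R <- random_rotation(17)
  shift <- matrix(c(1, -0.5, 2), n_atoms(ch$top), 3, byrow = TRUE)
  mob <- ch$xyz %*% R + shift
  fit <- superimpose(ch$xyz, mob)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$fitted, ch$xyz, tolerance = 1e-10)
  # reflection never sneaks in: mirrored input still yields det +1
  mir <- ch$xyz; mir[, 1] <- -mir[, 1]
  fit2 <- superimpose(ch$xyz, mir)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  expect_error(superimpose(ch$xyz[1:2, ], mob[1:2, ]))
  col <- cbind(1:5, 0, 0) * 0.1
  expect_error(superimpose(col, col), "collinear")
})

test_that("rmsd has its closed form for simple displacements", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- a
  b[, 3] <- b[, 3] + 0.3
  # identical up to translation: superposed RMSD is 0
  expect_lt(superimpose(a, b)$rmsd, 1e-12)
  # raw rmsd without fitting
  expect_equal(rmsd_value(a, b), 0.3, tolerance = 1e-12)
})

test_that("rmsd series fits each frame before measuring", {
  ch <- make_toy_chain(4, seed = 2)
  R <- random_rotation(3)
  fr <- list(ch$xyz, ch$xyz %*% R + 0.5, ch$xyz + 0.2)
  tr <- trajectory(fr, 0:2)
  rs <- rmsd_series(tr, ch$xyz)
  expect_equal(length(rs), 3)
  expect_lt(max(rs), 1e-10)    # rigid motions all fit back perfectly
})

test_that("two-state RMSF equals half the displacement", {
  # [DERIVED] atom alternating between two points d apart: rmsf = d/2.
  # Many atoms keep the fit from moving anything.
  n <- 8
  top <- topology(data.frame(name = "CA", sasa_type = "CH1",
                             resid = 1:n, resname = "X"))
  base <- cbind(seq_len(n) * 0.4, (seq_len(n) %% 3) * 0.2, 0)
  d <- 0.06
  f2 <- base; f2[4, 3] <- f2[4, 3] + d
  # fit over the unchanged atoms so the superposition is the identity
  tr <- trajectory(list(base, f2), 0:1)
  r <- rmsf(tr, fit_sel = setdiff(1:n, 4))
  expect_equal(r[4], d / 2, tolerance = 1e-10)
  expect_lt(max(r[-4]), 1e-10)
})

test_that("radius of gyration has its two-mass closed form", {
  top <- topology(data.frame(name = c("A", "B"), sasa_type = c("CH3", "CH3"),
                             resid = 1, resname = "X"))
  x <- rbind(c(0, 0, 0), c(0.8, 0, 0))
  # [DERIVED] equal masses distance d apart: Rgyr = d/2
  expect_equal(radius_of_gyration(x, top), 0.4, tolerance = 1e-12)
  # mass weighting pulls Rgyr toward the heavy atom
  top2 <- topology(data.frame(name = c("A", "B"), sasa_type = c("S", "H"),
                              resid = 1, resname = "X"))
  m <- top2$atoms$mass
  expect_equal(radius_of_gyration(x, top2),
               0.8 * sqrt(m[1] * m[2]) / sum(m), tolerance = 1e-12)
  # raw-sum variant keeps the literal mass-weighted sum
  expect_equal(radius_of_gyration(x, top, normalise = FALSE),
               0.4 * sqrt(2 * top$atoms$mass[1]), tolerance = 1e-12)
})

test_that("hydrogen-bond criterion applies strict boundary semantics", {
  crit <- hbond_criterion()
  expect_equal(crit$max_ha_nm, 0.25)
  expect_equal(crit$min_dha_deg, 135)
  # donor N-H ... acceptor O, linear: angle 180
  mk <- function(d_ha) {
    top <- topology(data.frame(name = c("N", "HN", "O"),
                               sasa_type = c("N", "H", "O"),
                               resid = c(1, 1, 2), resname = "X"),
                    rbind(c(1L, 2L)))
    # H at the origin so d_ha is represented exactly
    x <- rbind(c(-0.1, 0, 0), c(0, 0, 0), c(d_ha, 0, 0))
    hydrogen_bonds(x, top)
  }
  expect_equal(nrow(mk(0.20)), 1)
  expect_equal(nrow(mk(0.25)), 0)       # boundary excluded
  expect_equal(nrow(mk(0.2499)), 1)
  # bent geometry exactly at 135 degrees excluded, slightly above included
  mk_ang <- function(ang_deg) {
    top <- topology(data.frame(name = c("N", "HN", "O"),
                               sasa_type = c("N", "H", "O"),
                               resid = c(1, 1, 2), resname = "X"),
                    rbind(c(1L, 2L)))
    th <- (180 - ang_deg) * pi / 180
    a <- c(0.1 + 0.2 * cos(th), 0.2 * sin(th), 0)
    x <- rbind(c(0, 0, 0), c(0.1, 0, 0), a)
    hydrogen_bonds(x, top)
  }
  expect_equal(nrow(mk_ang(135)), 0)
  expect_equal(nrow(mk_ang(136)), 1)
  expect_equal(nrow(mk_ang(134)), 0)
})

test_that("hydrogen-bond occupancies average over frames", {
  top <- topology(data.frame(name = c("N", "HN", "O"),
                             sasa_type = c("N", "H", "O"),
                             resid = c(1, 1, 2), resname = "X"),
                  rbind(c(1L, 2L)))
  near <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0))
  far <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.8, 0, 0))
  tr <- trajectory(list(near, near, far, far), 0:3)
  hb <- hydrogen_bonds(tr, top)
  expect_equal(hb$occupancy, 0.5)
  expect_equal(hbond_extent(hb, n_reference = 1), 50)
})

test_that("torsion angles follow the signed IUPAC convention", {
  # +90: l atom on the +z side looking down j -> k
  x <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(abs(torsion_angle(x, 1:4)), 90, tolerance = 1e-12)
  xm <- x; xm[4, 3] <- -1
  expect_equal(torsion_angle(xm, 1:4), -torsion_angle(x, 1:4),
               tolerance = 1e-12)
  expect_error(torsion_angle(rbind(x[1:3, ], x[3, ]), 1:4))
})

test_that("torsion series embeds angles on the unit circle", {
  ch <- make_toy_chain(3, seed = 1)
  idx <- select_atoms(ch$top, "name CA")
  fr <- list(ch$xyz, ch$xyz + 0.01)
  tr <- trajectory(fr, 0:1)
  ts <- torsion_series(tr, c(1, 2, 3, 4))
  expect_equal(ncol(ts$values), 2)
  expect_equal(rowSums(ts$values^2), c(1, 1), tolerance = 1e-12)
  tsa <- torsion_series(tr, c(1, 2, 3, 4), embed = "angle")
  expect_equal(ncol(tsa$values), 1)
})

test_that("FFT autocorrelation equals the direct lag sum to 1e-10", {
  set.seed(31)
  x <- rnorm(400)
  ac <- autocorrelation(time_series(x, dt = 0.02))
  n <- length(x)
  direct <- vapply(0:(n - 1), function(t) {
    k <- n - t
    sum(x[1:k] * x[(1 + t):n]) / k
  }, numeric(1))
  direct <- direct / direct[1]
  expect_lt(max(abs(ac$acf - direct)), 1e-10)
  expect_equal(ac$acf[1], 1)
  expect_equal(ac$time[2], 0.02)
  # vector-valued series: dot-product correlation
  m <- cbind(x, rnorm(400))
  acm <- autocorrelation(time_series(m, dt = 1))
  expect_equal(acm$acf[1], 1)
  expect_error(autocorrelation(rep(0, 10)), "zero")
})

test_that("exponential ACF decays at the generating rate", {
  # OU process with known correlation time
  set.seed(7)
  th <- 0.2; n <- 60000
  x <- numeric(n)
  for (i in 2:n) x[i] <- x[i - 1] * (1 - th) + rnorm(1, sd = 0.1)
  ac <- autocorrelation(time_series(x, dt = 1))
  # fit log-linear over the first decade
  sel <- 1:12
  fit <- stats::lm(log(ac$acf[sel]) ~ ac$time[sel])
  expect_equal(unname(stats::coef(fit)[2]), log(1 - th), tolerance = 0.05)
})

test_that("spectral density of a cosine peaks at its frequency", {
  dt <- 0.05
  t <- seq(0, 500, by = dt)
  w0 <- 2
  x <- cos(w0 * t)
  ac <- autocorrelation(time_series(x, dt = dt))
  sd_ <- spectral_density(ac, fraction = 0.2, n_freq = 512)
  expect_equal(sd_$omega[which.max(sd_$density)], w0, tolerance = 0.05)
  expect_lte(max(sd_$omega), pi / dt + 1e-9)
})
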