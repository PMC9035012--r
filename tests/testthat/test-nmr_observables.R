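test_that("Karplus parameter sets and curve match the published relation", {
  pb <- karplus_params("backbone")
  expect_equal(c(pb$a, pb$b, pb$c), c(6.4, -1.4, 1.9))
  ps <- karplus_params("sidechain")
  expect_equal(c(ps$a, ps$b, ps$c), c(9.5, -1.6, 1.8))
  # [TRIVIAL] endpoint values
  expect_equal(karplus_j(0, pb), 6.4 - 1.4 + 1.9)
  expect_equal(karplus_j(180, pb), 6.4 + 1.4 + 1.9)
  # [DERIVED] frozen hand evaluation at 47.3 degrees
  expect_equal(karplus_j(47.3, pb), 3.893939904332, tolerance = 1e-10)
  ex <- karplus_extrema(pb)
  expect_equal(unname(ex["max"]), 9.7)
  # curve minimum at the interior vertex cos(theta) = -b/2a
  expect_equal(unname(ex["min"]), karplus_j(acos(1.4 / 12.8) * 180 / pi, pb),
               tolerance = 1e-12)
  expect_true(all(karplus_j(seq(0, 360, by = 0.5), pb) <= ex["max"] + 1e-12))
})

test_that("r^-3 averaging matches the frozen oracle and its bound", {
  # [DERIVED] (mean(c(0.2, 0.25, 0.3)^-3))^(-1/3)
  d <- c(0.2, 0.25, 0.3)
  expect_equal(noe_average_distance(d), 0.236763026570, tolerance = 1e-10)
  # never larger than the arithmetic mean; equal for constant distance
  expect_lt(noe_average_distance(d), mean(d))
  expect_equal(noe_average_distance(rep(0.27, 5)), 0.27, tolerance = 1e-12)
  expect_error(noe_average_distance(c(0.2, 0)), "zero")
  tr <- trajectory(list(rbind(c(0, 0, 0), c(0.2, 0, 0)),
                        rbind(c(0, 0, 0), c(0.3, 0, 0))), c(0, 1))
  expect_equal(noe_average_distance(tr, c(1, 2)),
               mean(c(0.2, 0.3)^-3)^(-1 / 3), tolerance = 1e-12)
})

test_that("wildcard groups sum r^-3 over all matching protons", {
  # [DERIVED] (0.25^-3 + 0.3^-3)^(-1/3)
  x <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(0, 0.3, 0))
  s <- implisolv:::group_r3_sum(x, 1, c(2, 3))
  expect_equal(s^(-1 / 3), 0.214703833813, tolerance = 1e-10)
})

test_that("virtual CH hydrogen is tetrahedrally symmetric", {
  ch <- make_toy_chain(2, seed = 1)
  vh <- build_virtual_hydrogens(ch$xyz, ch$top)
  ha <- vh$sites[vh$sites$name == "HA" & vh$sites$resid == 1, ]
  ca <- ha$parent
  hx <- vh$xyz[ha$index, ]
  expect_equal(sqrt(sum((hx - ch$xyz[ca, ])^2)), 0.1, tolerance = 1e-12)
  # H direction opposes the summed unit vectors to N, C and CB
  nb <- c(which(ch$top$atoms$resid == 1 & ch$top$atoms$name == "N"),
          which(ch$top$atoms$resid == 1 & ch$top$atoms$name == "C"),
          which(ch$top$atoms$resid == 1 & ch$top$atoms$name == "CB"))
  uh <- (hx - ch$xyz[ca, ]) / 0.1
  usum <- colSums(t(vapply(nb, function(j) {
    u <- ch$xyz[j, ] - ch$xyz[ca, ]; u / sqrt(sum(u^2))
  }, numeric(3))))
  expect_equal(uh, -usum / sqrt(sum(usum^2)), tolerance = 1e-10)
  # and it sits on the opposite side of every bond
  expect_true(all(vapply(nb, function(j)
    sum(uh * (ch$xyz[j, ] - ch$xyz[ca, ])) < 0, logical(1))))
})

test_that("prochiral CH2 pair is symmetric about the heavy-atom plane", {
  top <- topology(data.frame(name = c("CG", "CB", "CA"),
                             sasa_type = c("CH3", "CH2", "C"),
                             resid = 1, resname = "X"),
                  rbind(c(1L, 2L), c(2L, 3L)))
  x <- rbind(c(0.15, 0, 0), c(0, 0, 0), c(-0.1, 0.12, 0))
  vh <- build_virtual_hydrogens(x, top)
  hb <- vh$sites[vh$sites$parent == 2, ]
  expect_equal(sort(hb$name), c("HB2", "HB3"))
  h2 <- vh$xyz[hb$index[hb$name == "HB2"], ]
  h3 <- vh$xyz[hb$index[hb$name == "HB3"], ]
  expect_equal(sqrt(sum(h2^2)), 0.1, tolerance = 1e-12)
  expect_equal(sqrt(sum(h3^2)), 0.1, tolerance = 1e-12)
  # H-C-H angle is tetrahedral, and the pair mirrors through z = 0
  expect_equal(acos(sum(h2 * h3) / 0.01) * 180 / pi, 109.47,
               tolerance = 1e-6)
  expect_equal(h2[1:2], h3[1:2], tolerance = 1e-12)
  expect_equal(h2[3], -h3[3], tolerance = 1e-12)
})

test_that("amide hydrogen is planar and methyls collapse to pseudo-sites", {
  ch <- make_toy_chain(2, seed = 1)
  vh <- build_virtual_hydrogens(ch$xyz, ch$top)
  hn <- vh$sites[vh$sites$name == "HN", ]
  expect_equal(hn$resid, 2)          # only the second amide has 2 neighbours
  nidx <- hn$parent
  hx <- vh$xyz[hn$index, ]
  expect_equal(sqrt(sum((hx - ch$xyz[nidx, ])^2)), 0.1, tolerance = 1e-12)
  # coplanar with N and its two heavy neighbours
  prevc <- which(ch$top$atoms$resid == 1 & ch$top$atoms$name == "C")
  ca2 <- which(ch$top$atoms$resid == 2 & ch$top$atoms$name == "CA")
  nrm <- crossprod_vec <- function(a, b)
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  nv <- nrm(ch$xyz[prevc, ] - ch$xyz[nidx, ], ch$xyz[ca2, ] - ch$xyz[nidx, ])
  expect_lt(abs(sum((hx - ch$xyz[nidx, ]) * nv / sqrt(sum(nv^2)))), 1e-10)
  # CH3 pseudo-site sits exactly on the carbon
  hb <- vh$sites[vh$sites$name == "HB" & vh$sites$resid == 1, ]
  expect_equal(vh$xyz[hb$index, ], ch$xyz[hb$parent, ], tolerance = 1e-15)
  expect_equal(hb$kind, "CH3")
})

test_that("proton specs resolve exactly or by trailing wildcard", {
  ch <- make_toy_chain(2, seed = 1)
  vh <- build_virtual_hydrogens(ch$xyz, ch$top)
  one <- resolve_proton_spec("HA", 1, vh, ch$top)
  expect_length(one$indices, 1)
  expect_false(one$wildcard)
  star <- resolve_proton_spec("H*", 1, vh, ch$top)
  expect_gt(length(star$indices), 1)
  expect_true(star$wildcard)
  none <- resolve_proton_spec("HZ9", 1, vh, ch$top)
  expect_length(none$indices, 0)
})

test_that("pseudo-atom corrections table and endpoint kinds", {
  pc <- pseudoatom_corrections()
  look <- function(k) pc$correction_nm[pc$kind == k]
  expect_equal(look("CH3"), 0.10)
  expect_equal(look("CH2_wildcard"), 0.10)
  expect_equal(look("ring_wildcard"), 0.20)
  expect_equal(look("double_CH3"), 0.20)
  expect_equal(look("none"), 0.00)
  eck <- implisolv:::endpoint_correction_kind
  expect_equal(eck("CH1", FALSE), "none")
  expect_equal(eck("CH3", FALSE), "CH3")
  expect_equal(eck(c("CH2", "CH2"), TRUE), "CH2_wildcard")
  expect_equal(eck(c("CR1", "CR1"), TRUE), "ring_wildcard")
})

test_that("back-calculated couplings average the per-frame Karplus values", {
  ch <- make_toy_chain(3, seed = 2)
  rec <- data.frame(resid = 2, type = "backbone")
  j1 <- calc_j_couplings(ch$xyz, ch$top, rec)
  expect_true(j1$resolved)
  # compute the same thing by hand from the dihedral on the virtual sites
  vh <- build_virtual_hydrogens(ch$xyz, ch$top)
  site <- function(nm) vh$sites$index[vh$sites$resid == 2 &
                                        vh$sites$name == nm]
  at <- function(nm) which(ch$top$atoms$resid == 2 & ch$top$atoms$name == nm)
  th <- torsion_angle(vh$xyz, c(site("HN"), at("N"), at("CA"), site("HA")))
  expect_equal(j1$calc_hz, karplus_j(th, karplus_params("backbone")),
               tolerance = 1e-12)
  # residue 1 has no amide proton: unresolved, reported NA
  j0 <- calc_j_couplings(ch$xyz, ch$top,
                         data.frame(resid = 1, type = "backbone"))
  expect_false(j0$resolved)
  expect_true(is.na(j0$calc_hz))
})

test_that("ambiguous assignment minimises summed deviation, ties keep order", {
  res <- resolve_ambiguous_assignment(c(5, 9), c(8.8, 5.2))
  expect_true(res$swapped)
  expect_equal(res$exp_assigned[1, ], c(5.2, 8.8))
  res2 <- resolve_ambiguous_assignment(c(5, 9), c(5.1, 9.2))
  expect_false(res2$swapped)
  # exact tie: both pairings deviate equally, input order kept
  res3 <- resolve_ambiguous_assignment(c(5, 5), c(4, 6))
  expect_false(res3$swapped)
  # the optimum never exceeds either fixed pairing
  set.seed(8)
  cm <- matrix(runif(40, 2, 10), ncol = 2)
  em <- matrix(runif(40, 2, 10), ncol = 2)
  r <- resolve_ambiguous_assignment(cm, em)
  best <- rowSums(r$deviations)
  expect_true(all(best <= abs(cm[, 1] - em[, 1]) + abs(cm[, 2] - em[, 2]) + 1e-12))
  expect_true(all(best <= abs(cm[, 1] - em[, 2]) + abs(cm[, 2] - em[, 1]) + 1e-12))
})

test_that("order parameter hits its rigid and isotropic limits", {
  # rigid vector: S2 = 1
  fr <- replicate(50, rbind(c(0, 0, 0), c(0.1, 0, 0)), simplify = FALSE)
  tr <- trajectory(fr, seq_len(50) - 1)
  expect_equal(order_parameter(tr, 2, 1), 1, tolerance = 1e-12)
  # isotropic tumbling: S2 near 0
  set.seed(21)
  fri <- lapply(seq_len(4000), function(i) {
    u <- rnorm(3); u <- 0.1 * u / sqrt(sum(u^2))
    rbind(c(0, 0, 0), u)
  })
  tri <- trajectory(fri, seq_len(4000) - 1)
  expect_lt(order_parameter(tri, 2, 1), 0.05)
  expect_error(order_parameter(tr, 2, 1, window_ps = 1e6), "window")
})

test_that("cone-diffusion S2 matches the closed form", {
  # [DERIVED] S = cos(beta)(1 + cos(beta))/2 -> S2 = 0.140625 at 60 deg
  expect_equal(cone_order_parameter(60), 0.140625, tolerance = 1e-12)
  ct <- make_cone_trajectory(60, 20000, seed = 11)
  expect_equal(order_parameter(ct$traj, 2, 1), 0.140625, tolerance = 0.05)
})

test_that("deviation binning uses the published edges and thresholds", {
  spec <- implisolv:::.deviation_spec
  expect_equal(spec$noe$edges, c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30))
  expect_equal(spec$noe$threshold, 0.1)
  expect_equal(spec$j$edges, 1:5)
  expect_equal(spec$j$threshold, 2)
  expect_equal(spec$s2$edges, c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(spec$s2$threshold, 0.2)
  # half-open bins: a value on an edge falls in the upper bin
  h <- deviation_histogram_counts(c(0.049, 0.05, 0.1, 0.31), spec$noe$edges)
  expect_equal(unname(h), c(1, 1, 0, 0, 0, 1))
  # deviations below the first edge (here 0.5 Hz) are not histogrammed
  r <- deviation_report(c(5, 9.4), c(4.5, 6.1), kind = "j")
  expect_equal(r$n_significant, 1L)
  expect_equal(unname(r$histogram), c(0, 0, 1, 0, 0))
})

test_that("NOE violation report flags unresolved records, never drops them", {
  ch <- make_toy_chain(3, seed = 5)
  restr <- data.frame(
    resid_i = c(1, 1), atom_i = c("HA", "HQQ"),
    resid_j = c(2, 2), atom_j = c("HA", "HA"),
    bound_nm = c(0.25, 0.25))
  dc <- calc_noe_distances(ch$xyz, ch$top, restr)
  expect_equal(dc$resolved, c(TRUE, FALSE))
  rep_ <- noe_violation_report(dc)
  expect_equal(nrow(rep_$rejects), 1)
  expect_equal(rep_$n_restraints, 2)
  expect_length(rep_$violations, 1)
})
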