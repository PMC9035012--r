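test_that("parameter table carries the published radii, p_i and sigmas", {
  tab <- sasa_parameter_table()
  row <- function(nm) tab[tab$name == nm, ]
  expect_equal(row("O")$radius_nm, 0.150)
  expect_equal(row("O")$p_i, 0.926)
  expect_equal(row("O")$sigma_per_type, -7.2)
  expect_equal(row("O")$sigma_three_class, -7.3)
  expect_equal(row("CH3")$radius_nm, 0.200)
  expect_equal(row("CH3")$p_i, 0.880)
  expect_equal(row("CH3")$sigma_per_type, 3.3)
  expect_equal(row("CH3")$sigma_three_class, 4.1)
  expect_equal(row("OM")$sigma_per_type, -21.7)
  expect_equal(row("NL")$sigma_per_type, -26.1)
  expect_equal(row("NZ")$sigma_per_type, -13.3)
  # undefined radii stay NA and are excluded from surface evaluation
  expect_true(all(is.na(row("OW")$radius_nm)))
  expect_true(all(is.na(row("DUM")$radius_nm)))
  expect_true(all(is.na(row("CH4")$radius_nm)))
  # defined radius but undefined per-type sigma
  expect_false(is.na(row("OE")$radius_nm))
  expect_true(is.na(row("OE")$sigma_per_type))
})

test_that("parameter sets resolve with the documented defaults", {
  p <- sasa_params()
  expect_equal(p$R_solv, 0.14)
  expect_equal(p$p_first, 0.8875)
  expect_equal(p$p_next, 0.3516)
  expect_equal(unname(p$sigma["CH3"]), 3.3)
  p3 <- sasa_params("three-class")
  expect_equal(unname(p3$sigma["CH3"]), 4.1)
  # OE stays undefined in both sets
  expect_true(is.na(p3$sigma["OE"]))
})

test_that("isolated atom area is the full solvent-augmented sphere", {
  # [DERIVED] 4 pi (0.150 + 0.140)^2
  expect_equal(isolated_area("O"), 4 * pi * 0.29^2, tolerance = 1e-12)
  expect_equal(isolated_area("CH3"), 4 * pi * 0.34^2, tolerance = 1e-12)
})

test_that("pair reduction term is continuous and vanishes at the cutoff", {
  p <- sasa_params()
  cutoff <- 0.150 + 0.180 + 2 * 0.14  # O-CH1
  eps <- 1e-9
  expect_equal(overlap_reduction(cutoff + 0.01, "O", "CH1"), 0)
  expect_lt(overlap_reduction(cutoff - eps, "O", "CH1"), 1e-6)
  expect_gt(overlap_reduction(0.25, "O", "CH1"), 0)
  # asymmetric in the two atoms
  expect_false(isTRUE(all.equal(overlap_reduction(0.25, "O", "CH1"),
                                overlap_reduction(0.25, "CH1", "O"))))
  expect_error(overlap_reduction(0, "O", "CH1"))
  expect_error(overlap_reduction(0.2, "OW", "CH1"), "undefined")
})

test_that("areas and energy match an independent scalar oracle", {
  # [DERIVED] frozen from a naive scalar implementation of the
  # pairwise-reduction area formula, written without reference to the
  # package code, for the three_atom_system() configuration
  sys <- three_atom_system()
  sr <- sasa_energy_forces(sys$xyz, sys$top, sasa_params())
  expect_equal(sr$area,
               c(0.658319445095, 0.536580584811, 1.043643268369),
               tolerance = 1e-9)
  expect_equal(sr$energy, 0.743129003218, tolerance = 1e-9)
  expect_equal(sr$S[1], 4 * pi * 0.29^2, tolerance = 1e-12)
})

test_that("analytic SASA forces match finite differences to 1e-4", {
  ch <- make_toy_chain(4, seed = 3)
  p <- sasa_params()
  sr <- sasa_energy_forces(ch$xyz, ch$top, p)
  num <- fd_forces(ch$xyz,
                   function(x) sasa_energy_forces(x, ch$top, p)$energy)
  expect_lt(max(abs(sr$forces - num) / pmax(1, abs(num))), 1e-4)
})

test_that("energy is invariant and forces covariant under rigid motion", {
  sys <- three_atom_system()
  p <- sasa_params()
  sr <- sasa_energy_forces(sys$xyz, sys$top, p)
  R <- random_rotation(9)
  shift <- matrix(c(1.5, -2, 0.7), nrow(sys$xyz), 3, byrow = TRUE)
  x2 <- sys$xyz %*% R + shift
  sr2 <- sasa_energy_forces(x2, sys$top, p)
  expect_equal(sr2$energy, sr$energy, tolerance = 1e-10)
  expect_equal(sr2$area, sr$area, tolerance = 1e-10)
  expect_equal(sr2$forces, sr$forces %*% R, tolerance = 1e-8)
})

test_that("separating a pair monotonically grows both areas", {
  top <- topology(data.frame(name = c("A", "B"), sasa_type = c("O", "N"),
                             resid = 1, resname = "X"),
                  rbind(c(1L, 2L)))
  p <- sasa_params()
  rs <- seq(0.15, 0.61, by = 0.02)    # O-N cutoff is 0.585 nm
  areas <- t(vapply(rs, function(r)
    atomic_areas(rbind(c(0, 0, 0), c(r, 0, 0)), top, p), numeric(2)))
  expect_true(all(diff(areas[, 1]) >= 0))
  expect_true(all(diff(areas[, 2]) >= 0))
  # beyond the cutoff both reach the isolated-sphere value
  expect_equal(areas[nrow(areas), 1], isolated_area("O"), tolerance = 1e-12)
})

test_that("clamped reduction factors carry zero derivative", {
  # deeply overlapping unequal-radius pair drives 1 - p p_ij b/S outside
  # [0, 1]; the factor is clamped and the analytic force must still match
  # finite differences
  top <- topology(data.frame(name = c("A", "B"), sasa_type = c("O", "CH3"),
                             resid = 1, resname = "X"),
                  rbind(c(1L, 2L)))
  x <- rbind(c(0, 0, 0), c(0.02, 0, 0))
  p <- sasa_params()
  sr <- sasa_energy_forces(x, top, p)
  expect_true(any(sr$clamped))
  num <- fd_forces(x, function(xx) sasa_energy_forces(xx, top, p)$energy)
  expect_equal(sr$forces, num, tolerance = 1e-6)
})

test_that("undefined sigma raises unless explicitly overridden", {
  top <- topology(data.frame(name = c("OE1", "CB"),
                             sasa_type = c("OE", "CH3"),
                             resid = 1, resname = "X"))
  x <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_error(sasa_energy_forces(x, top, sasa_params()), "OE")
  sr <- sasa_energy_forces(x, top, sasa_params(),
                           allow_undefined_sigma = TRUE)
  expect_true(is.finite(sr$energy))
})

test_that("atoms with undefined radii are excluded, not silently dropped", {
  top <- topology(data.frame(name = c("D", "CB"),
                             sasa_type = c("DUM", "CH3"),
                             resid = 1, resname = "X",
                             mass = c(1, 15.035)))
  x <- rbind(c(0, 0, 0), c(0.05, 0, 0))
  sr <- sasa_energy_forces(x, top, sasa_params())
  expect_equal(sr$excluded, 1L)
  # the dummy neither gains area nor occludes its neighbour
  expect_equal(sr$area[2], isolated_area("CH3"), tolerance = 1e-12)
})

test_that("hydrophilic/hydrophobic class totals partition the surface", {
  ch <- make_toy_chain(4, seed = 3)
  sr <- sasa_energy_forces(ch$xyz, ch$top, sasa_params())
  ct <- sr$class_totals
  expect_equal(unname(ct["hydrophilic"] + ct["hydrophobic"]),
               unname(ct["total"]), tolerance = 1e-9)
  expect_equal(unname(ct["total"]), sum(sr$area), tolerance = 1e-9)
})

test_that("neighbour orders fall back to the distant-pair p_ij", {
  # directly bonded -> p_first, two bonds apart -> p_next, else 1
  ch <- make_toy_chain(2, seed = 1)
  omap <- implisolv:::neighbour_order_map(ch$top)
  expect_equal(omap(1, 2, 0.8875, 0.3516), 0.8875)  # N-CA
  expect_equal(omap(1, 3, 0.8875, 0.3516), 0.3516)  # N-C via CA
  expect_equal(omap(1, 9, 0.8875, 0.3516), 1)
})
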