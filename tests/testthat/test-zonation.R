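test_that("geometry and flow constructors validate their inputs", {
  g <- ref_geometry()
  expect_equal(g$A_cell, pi * ((0.02 + 0.01 + 0.05)^2 - (0.02 + 0.01)^2))
  expect_error(krogh_geometry(0, 1, 1, 1), "positive")
  expect_error(flow_conditions(-1, 0.2, 1, 0.1), "Q")
  expect_error(flow_conditions(1, 0, 1, 0.1), "c_in")
  expect_error(flow_conditions(1, 0.2, -1, 0.1), "non-negative")
})

test_that("no uptake gives a flat oxygen profile", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(vmax = 0))
  expect_true(all(prof$oxygen == 0.2))
  expect_false(prof$anoxic)
})

test_that("zero-order uptake gives the clamped linear closed form", {
  g <- ref_geometry()
  f <- ref_flow(vmax = 2, km = 0)
  prof <- axial_oxygen_profile(g, f, n_points = 41)
  expected <- pmax(0, f$c_in - g$A_cell * f$uptake_vmax * prof$z * g$L / f$Q)
  expect_equal(prof$oxygen, expected, tolerance = 1e-12)
  # steeper uptake reaches zero before the outlet and must flag anoxia
  f2 <- ref_flow(vmax = 50, km = 0)
  prof2 <- axial_oxygen_profile(g, f2, n_points = 41)
  expect_true(prof2$anoxic)
  expect_equal(min(prof2$oxygen), 0)
  expect_true(all(prof2$oxygen >= 0))
})

test_that("first-order uptake limit matches the exponential closed form", {
  g <- ref_geometry()
  f <- ref_flow(vmax = 1.2e8, km = 2e6)     # km/c_in = 1e7: deep first-order regime
  prof <- axial_oxygen_profile(g, f, n_points = 33)
  k1 <- g$A_cell * f$uptake_vmax / f$uptake_km / f$Q
  expected <- f$c_in * exp(-k1 * prof$z * g$L)
  expect_equal(prof$oxygen, expected, tolerance = 1e-6)
})

test_that("oxygen profile is non-increasing and scales as c(z; 2Q) = c(z/2; Q)", {
  g <- ref_geometry()
  f1 <- ref_flow(Q = 1)
  f2 <- ref_flow(Q = 2)
  z <- seq(0, 1, length.out = 21)
  p1 <- axial_oxygen_profile(g, f1, z = z)
  expect_true(all(diff(p1$oxygen) <= 1e-12))
  p2 <- axial_oxygen_profile(g, f2, z = z)
  p1_half <- axial_oxygen_profile(g, f1, z = z / 2)
  expect_equal(p2$oxygen, p1_half$oxygen, tolerance = 1e-8)
})

test_that("default mapping is monotone in the expected directions", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(), n_points = 12)
  zp <- zonal_parameter_field(prof, zonation_mapping())
  expect_true(all(diff(zp$k_450_field) > 0))   # rises toward centrilobular
  expect_true(all(diff(zp$beta_G_field) < 0))  # GSH production falls
  expect_true(all(zp$P0_field == zp$P0_field[1]))
  expect_identical(zp$nonmonotone, character(0))
  # endpoints hit the configured ranges
  m <- zonation_mapping()
  expect_equal(zp$k_450_field[1], m$k450_min)
  expect_equal(zp$k_450_field[length(zp$z)], m$k450_max)
})

test_that("a flat oxygen profile maps to constant fields", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(vmax = 0))
  zp <- zonal_parameter_field(prof, zonation_mapping())
  expect_equal(length(unique(zp$k_450_field)), 1L)
  expect_equal(length(unique(zp$beta_G_field)), 1L)
})

test_that("default mapping equals direct interpolation at every node", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(), n_points = 15)
  m <- zonation_mapping()
  zp <- zonal_parameter_field(prof, m)
  # independent route: interpolate on the oxygen axis with approx()
  oxy <- prof$oxygen
  ref <- approx(x = c(min(oxy), max(oxy)), y = c(m$k450_max, m$k450_min),
                xout = oxy)$y
  expect_equal(zp$k_450_field, ref, tolerance = 1e-12)
})

test_that("non-monotone custom mappings are accepted but flagged", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(), n_points = 15)
  zp <- zonal_parameter_field(prof, zonation_mapping(
    k450_fun = function(c) 0.3 + 0.1 * sin(40 * c)))
  expect_true("k_450" %in% zp$nonmonotone)
})

test_that("identical zones give identical terminal damage", {
  prof <- axial_oxygen_profile(ref_geometry(), ref_flow(vmax = 0),
                               n_points = 6)
  zp <- zonal_parameter_field(prof, zonation_mapping())
  inj <- simulate_sinusoid(zp, ref_params(), t_end = 24,
                           keep_trajectories = FALSE)
  expect_equal(length(unique(round(inj$map$terminal_T, 12))), 1L)
})

test_that("APAP-like zonation yields a monotone centrilobular damage gradient", {
  zp <- sinusoid_zones(ref_geometry(), ref_flow(),
                       zonation_mapping(P0 = 20), n_zones = 12)
  inj <- simulate_sinusoid(zp, ref_params(), t_end = 24,
                           keep_trajectories = FALSE)
  tt <- inj$map$terminal_T
  expect_true(all(diff(tt) >= 0))
  cls <- classify_injury(inj, threshold = mean(range(tt)))
  expect_identical(cls$pattern, "centrilobular")
})

test_that("a zone without bioactivation accumulates no adduct", {
  zp <- structure(list(z = c(0.25, 0.75), oxygen = c(0.2, 0.1),
                       k_450_field = c(0.3, 0), beta_G_field = c(2, 2),
                       P0_field = c(5, 5), anoxic = FALSE,
                       nonmonotone = character(0)),
                  class = "zonal_profile")
  inj <- simulate_sinusoid(zp, ref_params(), t_end = 24,
                           keep_trajectories = FALSE)
  expect_gt(inj$map$terminal_T[1], 0)
  expect_equal(inj$map$terminal_T[2], 0)
})

test_that("zones are independent: permuting zones permutes results", {
  zp <- sinusoid_zones(ref_geometry(), ref_flow(), zonation_mapping(),
                       n_zones = 6)
  perm <- c(4, 1, 6, 3, 2, 5)
  zp_perm <- zp
  for (f in c("z", "oxygen", "k_450_field", "beta_G_field", "P0_field")) {
    zp_perm[[f]] <- zp[[f]][perm]
  }
  inj <- simulate_sinusoid(zp, ref_params(), t_end = 24,
                           keep_trajectories = FALSE)
  inj_perm <- simulate_sinusoid(zp_perm, ref_params(), t_end = 24,
                                keep_trajectories = FALSE)
  expect_equal(inj_perm$map$terminal_T[order(perm)], inj$map$terminal_T)
})

test_that("injury classification covers the canonical lobular patterns", {
  z <- (seq_len(9) - 0.5) / 9
  mk <- function(tt) data.frame(z = z, terminal_T = tt)
  expect_identical(classify_injury(mk(rep(0.1, 9)), 1)$pattern, "none")
  expect_identical(classify_injury(mk(c(rep(0, 6), 2, 2, 2)), 1)$pattern,
                   "centrilobular")
  expect_identical(classify_injury(mk(c(2, 2, 2, rep(0, 6))), 1)$pattern,
                   "periportal")
  expect_identical(classify_injury(mk(rep(2, 9)), 1)$pattern, "panlobular")
  expect_identical(classify_injury(mk(c(0, 0, 0, 2, 2, 2, 0, 0, 0)), 1)$pattern,
                   "midzonal")
  # injury reaching the central tertile but sparing the portal tertile is
  # still read as centrilobular
  expect_identical(classify_injury(mk(c(0, 0, 0, 0, 2, 2, 2, 2, 2)), 1)$pattern,
                   "centrilobular")
  expect_error(classify_injury(data.frame(), 1), "empty")
  expect_error(classify_injury(mk(rep(1, 9)), -1), "non-negative")
})
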