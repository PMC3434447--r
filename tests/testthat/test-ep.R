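test_that("default electrostatic parameters match standard practice", {
  p <- ep_parameters()
  expect_equal(p$ionic_strength, 0.150)
  expect_equal(p$solute_dielectric, 2)
  expect_equal(p$solvent_dielectric, 78.54)
  expect_equal(p$temperature, 298.15)
  expect_equal(debye_kappa(p), 0.1273, tolerance = 1e-3)
  expect_equal(bjerrum_length(p), 7.136, tolerance = 1e-3)
})

test_that("zero charges give an identically zero grid", {
  a <- make_fixture("dipole")$atoms
  a$charge <- 0
  g <- compute_ep_grid(structure3d(a))
  expect_true(all(g$values == 0))
})

test_that("a single charge matches the closed-form screened Coulomb", {
  # independent hand evaluation of q*lB*exp(-kappa d)/d at d = 5 A
  e <- 1.602176634e-19; kB <- 1.380649e-23; eps0 <- 8.8541878128e-12
  NAv <- 6.02214076e23
  T <- 298.15; eps_s <- 78.54; I <- 0.150
  lB <- e^2 / (4 * pi * eps0 * eps_s * kB * T) * 1e10
  kap <- sqrt(2 * 1000 * NAv * I * e^2 / (eps0 * eps_s * kB * T)) * 1e-10
  expected5 <- lB * exp(-kap * 5) / 5
  s <- one_atom_structure(charge = 1)
  geo <- list(origin = c(-6, -6, -6), spacing = 1, counts = c(13L, 13L, 13L))
  g <- compute_ep_grid(s, ep_parameters(), geometry = geo)
  expect_equal(g$values[12, 7, 7], expected5, tolerance = 1e-10)
  # brute-force double loop on a multi-atom fixture
  s2 <- random_structure(7, seed = 8)
  geo2 <- list(origin = c(-7, -7, -7), spacing = 2.5, counts = c(7L, 7L, 7L))
  g2 <- compute_ep_grid(s2, ep_parameters(), geometry = geo2)
  q <- s2$atoms$charge; pos <- atom_coords_helper(s2)
  for (t in 1:10) {
    idx <- c(sample(7, 1), sample(7, 1), sample(7, 1))
    r <- geo2$origin + (idx - 1) * geo2$spacing
    d <- pmax(sqrt(colSums((t(pos) - r)^2)), 0.1)
    expect_equal(g2$values[idx[1], idx[2], idx[3]],
                 sum(lB * q * exp(-kap * d) / d), tolerance = 1e-10)
  }
})

test_that("a +/- pair is antisymmetric under the mirror", {
  s <- make_fixture("dipole")  # +1 e at x = -3, -1 e at x = +3
  geo <- list(origin = c(-8, -5, -5), spacing = 1, counts = c(17L, 11L, 11L))
  g <- compute_ep_grid(s, geometry = geo)
  mirrored <- g$values[17:1, , ]
  expect_equal(g$values, -mirrored, tolerance = 1e-10)
})

test_that("zero ionic strength recovers the plain Coulomb potential", {
  p0 <- ep_parameters(ionic_strength = 0)
  expect_equal(debye_kappa(p0), 0)
  s <- one_atom_structure(charge = 1)
  geo <- list(origin = c(-5, -5, -5), spacing = 1, counts = c(11L, 11L, 11L))
  g <- compute_ep_grid(s, p0, geometry = geo)
  expect_equal(g$values[11, 6, 6], bjerrum_length(p0) / 5, tolerance = 1e-12)
})

test_that("potential magnitude decays monotonically along a grid axis", {
  s <- one_atom_structure(charge = 1)
  geo <- list(origin = c(0, 0, 0), spacing = 1, counts = c(15L, 2L, 2L))
  g <- compute_ep_grid(s, geometry = geo)
  vals <- g$values[, 1, 1]
  expect_true(all(diff(vals) < 0))
})

test_that("net_charge sums charges and guards missing ones", {
  a <- make_fixture("dipole")$atoms[c(1, 2, 1), ]
  a$serial <- 1:3
  a$charge <- c(0.5, -0.5, 1.0)
  expect_equal(net_charge(structure3d(a)), 1.0)
  a$charge <- c(-0.7, -0.5, 0.2)
  expect_lt(net_charge(structure3d(a)), 0)
  a$charge <- NA_real_
  expect_error(net_charge(structure3d(a)), "PQR")
  s <- structure3d(a)
  expect_error(compute_ep_grid(s), "charge")
})

test_that("load_ep_grid delegates to the DX reader and tags units", {
  s <- one_atom_structure(charge = 1)
  g <- compute_ep_grid(s)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  g2 <- load_ep_grid(path)
  expect_identical(g2$counts, g$counts)
  expect_equal(g2$values, g$values, tolerance = 0)
  expect_identical(attr(g2, "units"), "as-labeled")
  writeLines("garbage header", path)
  expect_error(load_ep_grid(path), "dialect")
})
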