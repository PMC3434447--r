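test_that("the testa kernel is exponential with kernel(0) = 1", {
  k <- mlp_formula("testa")$kernel
  expect_equal(k(0), 1)
  expect_equal(k(2), exp(-1))
  # one atom with f = 1 at the origin: grid value at distance 2 is e^-1
  s <- one_atom_structure(f = 1)
  g <- compute_mlp_grid(s, spacing = 2, padding = 4)
  at <- grid_interpolate(g, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(at[1], 1, tolerance = 1e-12)
  expect_equal(at[2], exp(-1), tolerance = 1e-12)
})

test_that("all named kernels decay and are finite at zero", {
  for (nm in c("testa", "fauchere", "dubost", "brasseur")) {
    k <- mlp_formula(nm)$kernel
    expect_true(is.finite(k(0)))
    expect_lt(k(50), k(0) * 0.1)
  }
})

test_that("the MLP grid is additive over atoms", {
  a <- make_fixture("dipole")
  geo <- list(origin = c(-8, -5, -5), spacing = 1, counts = c(17L, 11L, 11L))
  both <- compute_mlp_grid(a, geometry = geo)
  one <- structure3d(a$atoms[1, ]); two <- structure3d(a$atoms[2, ])
  g1 <- compute_mlp_grid(one, geometry = geo)
  g2 <- compute_mlp_grid(two, geometry = geo)
  expect_equal(both$values, g1$values + g2$values, tolerance = 1e-12)
})

test_that("the grid matches a naive triple-loop oracle to 1e-10", {
  for (seed in 1:3) {
    s <- random_structure(n = sample(2:10, 1), seed = seed)
    g <- compute_mlp_grid(s, spacing = 2, padding = 3, cutoff = Inf)
    expect_true(all(g$counts <= 12L))
    f <- s$atoms$f; pos <- atom_coords_helper(s)
    for (probe_i in seq_len(15)) {
      idx <- c(sample(g$counts[1], 1), sample(g$counts[2], 1),
               sample(g$counts[3], 1))
      r <- g$origin + (idx - 1) * g$spacing
      d <- sqrt(colSums((t(pos) - r)^2))
      expect_equal(g$values[idx[1], idx[2], idx[3]], sum(f * exp(-d / 2)),
                   tolerance = 1e-10)
    }
  }
})

test_that("MLP is translation-equivariant", {
  s <- random_structure(6, seed = 4)
  shift <- c(7.25, -3.5, 11)
  g0 <- compute_mlp_grid(s, spacing = 1.5, padding = 3)
  s2 <- s
  s2$atoms$x <- s$atoms$x + shift[1]
  s2$atoms$y <- s$atoms$y + shift[2]
  s2$atoms$z <- s$atoms$z + shift[3]
  g1 <- compute_mlp_grid(structure3d(s2$atoms),
                         geometry = list(origin = g0$origin + shift,
                                         spacing = g0$spacing,
                                         counts = g0$counts))
  expect_equal(g1$values, g0$values, tolerance = 1e-10)
})

test_that("spacing defaults to 1 Angstrom and overrides are honored", {
  expect_identical(default_spacing(), 1.0)
  s <- one_atom_structure()
  g <- compute_mlp_grid(s)
  expect_equal(g$spacing, c(1, 1, 1))
  g2 <- compute_mlp_grid(s, spacing = 0.5)
  expect_equal(g2$spacing, c(0.5, 0.5, 0.5))
  expect_error(compute_mlp_grid(s, spacing = 0), "spacing")
  expect_error(compute_mlp_grid(s, spacing = -1), "spacing")
})

test_that("the shipped library covers standard amino acids with a total lookup", {
  lib <- read_lipophilic_library()
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  atoms <- data.frame(serial = seq_along(aa3), name = "CA", element = "C",
                      residue_name = aa3, residue_id = seq_along(aa3),
                      chain = "A", x = 0, y = 0, z = 0)
  vals <- lipophilic_values(lib, structure3d(atoms))
  expect_length(vals, 20L)
  expect_true(all(is.finite(vals)))
  # hydrogens resolve through the element fallback
  h <- data.frame(serial = 1L, name = "HB2", element = "H",
                  residue_name = "ALA", residue_id = 1L, chain = "A",
                  x = 0, y = 0, z = 0)
  expect_true(is.finite(lipophilic_values(lib, structure3d(h))))
  # unknown element without fallback is a named error
  u <- h; u$name <- "UQ1"; u$element <- "UQ"; u$residue_name <- "XXX"
  expect_error(lipophilic_values(lib, structure3d(u)), "XXX")
})

test_that("surface MLP values on a protein-like fixture stay in the working range", {
  s <- make_fixture("mini_helix", rng_seed = 2)
  s$atoms$f <- NULL  # use the shipped library
  mesh <- build_surface(s, voxel = 0.8)
  g <- compute_mlp_grid(s)
  mesh <- sample_grid_at_vertices(g, mesh, "mlp")
  inside <- mean(mesh$channels$mlp >= -3 & mesh$channels$mlp <= 1)
  expect_gt(inside, 0.5)
})
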