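test_that("trilinear sampling is exact at nodes and for affine fields", {
  g <- grid_from_function(function(x, y, z) 2 * x - y + 3 * z,
                          origin = c(-1, -2, 0), spacing = c(0.5, 1, 0.75),
                          counts = c(7L, 5L, 6L))
  # node exactness
  g$values[3, 2, 4] <- 2.5
  node <- g$origin + (c(3, 2, 4) - 1) * g$spacing
  expect_equal(grid_interpolate(g, node), 2.5, tolerance = 1e-12)
  # affine exactness at random interior points
  g <- grid_from_function(function(x, y, z) 2 * x - y + 3 * z,
                          origin = c(-1, -2, 0), spacing = c(0.5, 1, 0.75),
                          counts = c(7L, 5L, 6L))
  set.seed(1)
  pts <- cbind(stats::runif(200, -1, 2), stats::runif(200, -2, 2),
               stats::runif(200, 0, 3.7))
  expect_equal(grid_interpolate(g, pts),
               2 * pts[, 1] - pts[, 2] + 3 * pts[, 3], tolerance = 1e-12)
  # constant field
  gc <- grid_from_function(function(x, y, z) x * 0 + 4.25, counts = c(3L, 3L, 3L))
  expect_equal(grid_interpolate(gc, cbind(0.3, 1.1, 1.9)), 4.25,
               tolerance = 1e-12)
})

test_that("trilinear sampling equals the 8-corner weighted sum", {
  set.seed(99)
  g <- scalar_grid(c(0, 0, 0), c(1, 1.5, 2), c(6L, 5L, 4L),
                   stats::rnorm(120))
  pts <- cbind(stats::runif(1000, 0, 5), stats::runif(1000, 0, 6),
               stats::runif(1000, 0, 6))
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    u <- pts[i, ] / g$spacing
    i0 <- pmin(floor(u), g$counts - 2); f <- u - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * g$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }, numeric(1))
  expect_equal(grid_interpolate(g, pts), brute, tolerance = 1e-12)
})

test_that("vertices outside the grid raise an error naming the vertex", {
  g <- grid_from_function(function(x, y, z) x, counts = c(3L, 3L, 3L))
  mesh <- triangle_mesh(rbind(c(1, 1, 1), c(9, 0, 0), c(0, 1, 0)),
                        rbind(c(1L, 2L, 3L)))
  expect_error(sample_grid_at_vertices(g, mesh, "ep"), "vertex 2")
  mesh_in <- triangle_mesh(rbind(c(1, 1, 1), c(2, 0, 0), c(0, 1, 0)),
                           rbind(c(1L, 2L, 3L)))
  out <- sample_grid_at_vertices(g, mesh_in, "ep")
  expect_equal(out$channels$ep, c(1, 2, 0), tolerance = 1e-12)
})

test_that("the gray map hits its knots, clamps and stays monotone", {
  expect_equal(mlp_to_gray(c(-3, 0, 1)), c(0, 0.5, 1))
  expect_equal(mlp_to_gray(c(-5, 4)), c(0, 1))       # clamp
  expect_equal(mlp_to_gray(-1.5), 0.25)
  expect_equal(mlp_to_gray(0.5), 0.75)
  x <- seq(-6, 3, by = 0.05)
  expect_true(all(diff(mlp_to_gray(x)) >= 0))
  # idempotence on already-clamped input
  g1 <- mlp_to_gray(x)
  expect_equal(mlp_to_gray(clamp_helper(x)), g1)
})

test_that("contrast and brightness act about mid-gray and re-clamp", {
  p <- gray_map_params(contrast = 2, brightness = 0)
  expect_equal(mlp_to_gray(0, p), 0.5)
  expect_equal(mlp_to_gray(-1.5, p), 0)     # (0.25-0.5)*2+0.5
  p2 <- gray_map_params(contrast = 1, brightness = 0.25)
  expect_equal(mlp_to_gray(0, p2), 0.75)
  expect_equal(mlp_to_gray(1, p2), 1)       # clamped
  expect_error(gray_map_params(in_low = 1, in_mid = 0), "knots")
})

test_that("material channels encode shiny-smooth vs rough-dull", {
  ch <- gray_to_material_channels(c(1, 0, 0.5))
  expect_equal(ch$specular, c(1, 0, 0.5))
  expect_equal(ch$noise_amplitude, c(0, 1, 0.5))
  expect_equal(ch$roughness, c(0, 1, 0.5))
  expect_error(gray_to_material_channels(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("channel arrays always length-match the vertex count", {
  m <- regular_tetra_mesh(mlp = c(-3, 0, 0.5, 1))
  m <- add_material_channels(m)
  nv <- nrow(m$vertices)
  for (nm in names(m$channels)) expect_length(m$channels[[nm]], nv)
  expect_error(set_channel(m, "ep", 1:3), "length")
  expect_error(triangle_mesh(m$vertices, m$triangles, list(ep = 1:5)),
               "channel")
  # noise preview is seeded and amplitude-scaled
  n1 <- noise_preview(m, rng_seed = 4)
  n2 <- noise_preview(m, rng_seed = 4)
  expect_identical(n1, n2)
  expect_equal(abs(n1) > 0, m$channels$noise_amplitude > 0)
})
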