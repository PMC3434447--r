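test_that("a lone atom yields a closed sphere with the analytic area", {
  s <- one_atom_structure(radius = 1.5)
  mesh <- build_surface(s, voxel = 0.25, probe = 1.4)
  st <- mesh_statistics(mesh)
  expect_true(st$watertight)
  expect_equal(st$euler_characteristic, 2L)
  expect_lt(abs(st$area_total - 4 * pi * 2.9^2) / (4 * pi * 2.9^2), 0.05)
  # surface radius within 3% of radius + probe
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(r - 2.9)) / 2.9, 0.03)
  expect_true(point_in_mesh(c(0, 0, 0), mesh))
})

test_that("mean edge length tracks the voxel size within a factor of 2", {
  s <- one_atom_structure(radius = 2)
  for (voxel in c(1, 0.5)) {
    st <- mesh_statistics(build_surface(s, voxel = voxel))
    expect_gt(st$mean_edge_length, voxel / 2)
    expect_lt(st$mean_edge_length, voxel * 2)
  }
})

test_that("distant atoms give two watertight components enclosing their centers", {
  a <- make_fixture("dipole")$atoms
  a$x <- c(0, 100)
  s <- structure3d(a)
  mesh <- build_surface(s, voxel = 1)
  comp <- surfscape:::mesh_components(mesh)
  expect_equal(max(comp), 2L)
  for (cmp in 1:2) {
    sub <- surfscape:::mesh_subset(mesh, comp == cmp)
    expect_true(is_watertight(sub))
  }
  expect_true(all(point_in_mesh(cbind(c(0, 100), 0, 0), mesh)))
})

test_that("area error shrinks monotonically as the voxel shrinks", {
  for (radius in c(1.2, 2.5, 4)) {
    s <- one_atom_structure(radius = radius)
    target <- 4 * pi * (radius + 1.4)^2
    errs <- vapply(c(1, 0.6, 0.35), function(vox) {
      abs(mesh_statistics(build_surface(s, voxel = vox,
                                        smooth_iterations = 0L))$area_total -
          target) / target
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("all atom centers lie inside the generated surface", {
  s <- make_fixture("mini_helix", rng_seed = 9)
  mesh <- build_surface(s, voxel = 0.8)
  expect_true(all(point_in_mesh(atom_coords_helper(s), mesh)))
})

test_that("too-coarse voxels are a resolution error", {
  s <- one_atom_structure(radius = 1.2)
  expect_error(build_surface(s, voxel = 1.3), "resolution")
})

test_that("mesh statistics report uniformity and openness correctly", {
  st <- mesh_statistics(regular_tetra_mesh())
  expect_equal(st$n_triangles, 4L)
  expect_equal(st$area_cv, 0, tolerance = 1e-12)
  expect_true(st$watertight)
  # open fan: drop one face of the tetrahedron
  tm <- regular_tetra_mesh()
  open_mesh <- triangle_mesh(tm$vertices, tm$triangles[1:3, ])
  expect_false(is_watertight(open_mesh))
  expect_false(mesh_statistics(open_mesh)$watertight)
})
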