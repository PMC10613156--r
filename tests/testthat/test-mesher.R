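# Implicit-geometry mesher: volume accuracy against closed forms,
# watertightness, and element validity.

test_that("truncated-ellipsoid mesh volume matches the closed-form integral", {
  a <- 0.02; c <- 0.04; t <- 0.5
  phi <- imp_intersect(imp_ellipsoid(c(0, 0, 0), c(a, a, c)),
                       imp_halfspace_z(t * c))
  bb <- rbind(c(-0.023, -0.023, -0.043), c(0.023, 0.023, 0.023))
  m <- voxel_tet_mesh(phi, bb, 0.002)
  # oracle: V = pi a^2 c (2/3 + t - t^3/3) for the part below z = t*c
  v_exact <- pi * a^2 * c * (2 / 3 + t - t^3 / 3)
  expect_lt(abs(mesh_volume(m) - v_exact) / v_exact, 0.01)
  expect_true(all(mesh_cell_volumes(m) > 0))
})

test_that("sphere mesh volume converges and the boundary is watertight", {
  r <- 0.015
  phi <- imp_sphere(c(0, 0, 0), r)
  bb <- rbind(rep(-r - 0.005, 3), rep(r + 0.005, 3))
  m <- voxel_tet_mesh(phi, bb, 0.002)
  v_exact <- 4 / 3 * pi * r^3
  expect_lt(abs(mesh_volume(m) - v_exact) / v_exact, 0.01)
  # watertight: divergence-theorem volume over the boundary faces equals the
  # summed cell volumes
  expect_equal(surface_enclosed_volume(m$points, m$faces), mesh_volume(m),
               tolerance = 1e-12)
  # closed 2-manifold: every boundary edge is shared by exactly two faces
  e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2L))
})

test_that("capped-cylinder mesh respects the analytic volume", {
  r <- 0.004; L <- 0.02; h <- 8e-4
  cyl <- imp_cylinder_z(c(0, 0), r, 0, L)
  bb <- rbind(c(-r - 2.5 * h, -r - 2.5 * h, -2 * h),
              c(r + 2.5 * h, r + 2.5 * h, L + 2 * h))
  m <- voxel_tet_mesh(cyl, bb, h)
  expect_lt(abs(mesh_volume(m) - pi * r^2 * L) / (pi * r^2 * L), 0.015)
})

test_that("degenerate inputs are rejected", {
  expect_error(voxel_tet_mesh(imp_sphere(c(0, 0, 0), 0.01),
                              rbind(c(0, 0, 0), c(1e-4, 1e-4, 1e-4)), 1e-3),
               "too small")
  expect_error(lh_shape_controls(mv_radius = -1), "degenerate")
})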