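# Interior extension of boundary displacements, ALE mesh velocity, and the
# geometric conservation check.

test_that("extension reproduces trivial and linear boundary fields", {
  g <- heart_geom_h()
  # homogeneous coefficients: rigid and constant-strain modes are exact
  ext <- extension_operator(g$mesh, stiffen = 0)
  nb <- length(ext$boundary_nodes)
  # zero data -> zero field
  d0 <- extend_displacement(ext, matrix(0, nb, 3))
  expect_equal(max(abs(d0)), 0)
  # uniform translation -> uniform translation (zero strain energy mode)
  cvec <- c(1e-3, 2e-3, -1e-3)
  dc <- extend_displacement(ext, matrix(rep(cvec, each = nb), ncol = 3))
  expect_equal(sweep(dc, 2, cvec), 0 * dc, tolerance = 1e-10)
  # linear boundary field -> linear interior field (constant-strain mode)
  B <- matrix(c(0.01, 0.002, 0, -0.003, 0.005, 0.001, 0, 0.002, -0.008), 3)
  bd <- g$mesh$points[ext$boundary_nodes, ] %*% t(B)
  dl <- extend_displacement(ext, bd)
  expect_equal(dl, g$mesh$points %*% t(B), tolerance = 1e-6)
})

test_that("extension operator is linear", {
  g <- heart_geom_h()
  ext <- extension_operator(g$mesh, type = "harmonic", stiffen = 0)
  nb <- length(ext$boundary_nodes)
  set.seed(1)
  d1 <- matrix(rnorm(nb * 3, sd = 1e-3), ncol = 3)
  d2 <- matrix(rnorm(nb * 3, sd = 1e-3), ncol = 3)
  lhs <- extend_displacement(ext, 2 * d1 - 0.5 * d2)
  rhs <- 2 * extend_displacement(ext, d1) - 0.5 * extend_displacement(ext, d2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("mesh velocity is the exact backward difference", {
  d_old <- matrix(1:12, 4)
  v <- c(0.3, -0.1, 2)
  d_new <- d_old + matrix(rep(v, each = 4), ncol = 3) * 2e-3
  expect_equal(mesh_velocity(d_new, d_old, 2e-3),
               matrix(rep(v, each = 4), ncol = 3))
  # static frames give zero velocity
  expect_equal(mesh_velocity(d_old, d_old, 1e-3), 0 * d_old)
})

test_that("geometric conservation: volume rate equals the ALE boundary flux", {
  g <- heart_geom_h()
  mo <- heart_motion_h()
  cm <- continuous_motion(mo)
  ext <- extension_operator(g$mesh)
  lv_surf <- lhflow:::region_closed_surface(g$mesh, g$cell_region == 1L)
  ref <- g$mesh$points
  dt <- 1e-3
  rel_err <- vapply(c(0.08, 0.16, 0.40, 0.70) * mo$period_T, function(t0) {
    c1 <- ref + extend_displacement(ext, interpolate_displacement(cm, t0))
    c2 <- ref + extend_displacement(ext, interpolate_displacement(cm, t0 + dt))
    uale <- (c2 - c1) / dt
    dVdt <- (surface_enclosed_volume(c2, lv_surf) -
               surface_enclosed_volume(c1, lv_surf)) / dt
    fg <- face_geometry(c2, lv_surf)
    un <- rowSums(matrix(uale[lv_surf, 1], ncol = 3) / 3) * fg$normal[, 1] +
      rowSums(matrix(uale[lv_surf, 2], ncol = 3) / 3) * fg$normal[, 2] +
      rowSums(matrix(uale[lv_surf, 3], ncol = 3) / 3) * fg$normal[, 3]
    abs(sum(fg$area * un) - dVdt) / max(abs(dVdt), 1e-9)
  }, numeric(1))
  expect_lt(max(rel_err), 0.01)
})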