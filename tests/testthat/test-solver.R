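# Flow solver: subgrid-viscosity closure, boundary waveforms, analytic tube
# benchmarks, and energy behaviour.

test_that("sigma-model viscosity matches hand-computed singular values", {
  # diagonal gradient: singular values are |entries|
  gmat <- matrix(0, 1, 9); gmat[1, c(1, 5, 9)] <- c(3, 2, 1)
  # oracle: D = s3 (s1-s2)(s2-s3)/s1^2 = 1*(3-2)*(2-1)/9 = 1/9
  expect_equal(sigma_subgrid_viscosity(gmat, 1e-3, 1060, 1.5),
               1060 * (1.5e-3)^2 * (1 / 9), tolerance = 1e-12)
  # planar (two-component) flow: third singular value is 0
  gpl <- matrix(0, 1, 9); gpl[1, c(1, 2, 4, 5)] <- c(1.3, -0.7, 2.1, 0.4)
  expect_equal(sigma_subgrid_viscosity(gpl, 1e-3, 1060, 1.5), 0)
  # pure rotation (antisymmetric): s1 = s2, s3 = 0 -> zero viscosity;
  # verified against R's own SVD as the independent oracle
  grot <- matrix(0, 1, 9); grot[1, 2] <- 5; grot[1, 4] <- -5
  sv <- svd(matrix(grot, 3, 3, byrow = TRUE))$d
  expect_equal(sv[1], sv[2])
  expect_equal(sigma_subgrid_viscosity(grot, 1e-3, 1060, 1.5), 0)
  expect_error(sigma_subgrid_viscosity(matrix(NaN, 1, 9), 1e-3, 1060),
               "non-finite")
})

test_that("boundary pressure waveforms match the imposed levels", {
  ph <- lh_scenario("healthy")
  # constant venous pressure of 10 mmHg = 1333.22 Pa
  for (t in c(0, 0.2, 0.45, 0.88)) {
    expect_equal(pressure_waveforms(t, ph)$p_pv, 1333.22)
  }
  # periodicity of both waveforms
  w1 <- pressure_waveforms(0.31, ph)
  w2 <- pressure_waveforms(0.31 + ph$period_T, ph)
  expect_equal(w1$p_ar, w2$p_ar)
  pr <- lh_scenario("regurgitant")
  # elevated venous profile reaches the configured peak (at mid-window)
  t_pk <- (0.05 + pr$t_es_frac + 0.12) / 2 * pr$period_T
  expect_equal(pressure_waveforms(t_pk, pr)$p_pv, pr$venous_peak)
  tt <- seq(0, pr$period_T, length.out = 400)
  ppv <- vapply(tt, function(t) pressure_waveforms(t, pr)$p_pv, numeric(1))
  expect_equal(min(ppv), pr$venous_pressure)
})

test_that("steady pressure-driven tube flow recovers Poiseuille", {
  pz <- poiseuille_result()
  expect_lt(pz$l2, 0.03)
  # wall shear stress within 5% of the analytic balance a dp / (2 L)
  expect_lt(abs(pz$wss_mean - pz$wss_exact) / pz$wss_exact, 0.05)
})

test_that("oscillatory tube flow follows the analytic series", {
  wz <- womersley_result()
  expect_lt(wz$err, 0.05)
})

test_that("zero data keep a zero state; kinetic energy decays unforced", {
  fix <- tube_fixture()
  cfg <- solver_config(dt = 2e-3, use_les = FALSE)
  pr <- flow_setup(fix$mesh, fix$wall_nodes, fix$open_nodes, fix$open_faces,
                   fluid_properties(1000, 0.0105), cfg)
  st <- flow_state_init(pr)
  pbc <- rep(0, length(fix$open_nodes))
  wallv <- matrix(0, length(fix$wall_nodes), 3)
  uale <- matrix(0, pr$n, 3)
  st1 <- advance_time_step(pr, st, fix$mesh$points, uale, wallv, pbc)
  expect_equal(max(abs(st1$u)), 0)
  expect_lt(max(abs(st1$p)), 1e-6)
  # seed a swirl and let it decay with zero forcing
  set.seed(7)
  m <- fix$mesh
  st1$u <- cbind(-m$points[, 2], m$points[, 1], 0) * 20
  st1$u[fix$wall_nodes, ] <- 0
  ke <- numeric(25)
  for (k in 1:25) {
    st1 <- advance_time_step(pr, st1, m$points, uale, wallv, pbc)
    ke[k] <- flow_kinetic_energy(pr, st1, m$points)
  }
  expect_true(all(diff(ke) < 1e-12))
})

test_that("adding the sigma closure never decreases dissipation", {
  fix <- tube_fixture()
  m <- fix$mesh
  cfg <- solver_config(dt = 2e-3, use_les = TRUE, delta = m$h)
  pr <- flow_setup(m, fix$wall_nodes, fix$open_nodes, fix$open_faces,
                   fluid_properties(1000, 0.0035), cfg)
  st <- flow_state_init(pr)
  # a swirly, fully 3D state
  set.seed(11)
  st$u <- cbind(sin(500 * m$points[, 2]) + 0.3 * m$points[, 3] * 50,
                cos(500 * m$points[, 1]),
                sin(400 * m$points[, 1]) * 0.5) * 0.3
  st$u[fix$wall_nodes, ] <- 0
  pbc <- rep(0, length(fix$open_nodes))
  wallv <- matrix(0, length(fix$wall_nodes), 3)
  uale <- matrix(0, pr$n, 3)
  st_les <- advance_time_step(pr, st, m$points, uale, wallv, pbc)
  expect_true(any(st_les$mu_sgs > 0))
  expect_true(all(st_les$mu_sgs >= 0))
  d_with <- flow_dissipation(pr, st_les, m$points, include_sgs = TRUE)
  d_without <- flow_dissipation(pr, st_les, m$points, include_sgs = FALSE)
  expect_gte(d_with, d_without)
})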