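# Resistive valve surfaces: smoothed-layer kernel, on-off switching rules,
# section flow rates, sealing under a pressure load, and domain attachment.

test_that("resistive layer kernel has compact support, peak and unit mass", {
  g <- heart_geom_h()
  v <- valve_surface(g, "mitral", "closed", eps_gamma = 0.75e-3)
  ctr <- c(g$shape$mv_center_x, 0, g$z_mv)
  # on the surface: peak value 1/eps
  expect_equal(riis_delta(rbind(ctr), v), 1 / v$eps_gamma, tolerance = 1e-6)
  # outside the support: zero at distance 2 eps
  expect_equal(riis_delta(rbind(ctr + c(0, 0, 2 * v$eps_gamma)), v), 0)
  # unit line integral across the layer along the surface normal
  dd <- seq(-2 * v$eps_gamma, 2 * v$eps_gamma, length.out = 801)
  vals <- riis_delta(cbind(ctr[1], ctr[2], g$z_mv + dd), v)
  mass <- sum(vals) * (dd[2] - dd[1]) # midpoint quadrature oracle
  expect_lt(abs(mass - 1), 0.02)
})

test_that("on-off switching follows the pressure/flow rules with the guard", {
  T <- 0.8
  st <- valve_state_init(mv = "closed", av = "closed",
                         guard_frac = 0.77 / 0.8)
  # closed MV opens on positive transvalvular pressure
  st <- update_valve_state(st, dp_av = -100, dp_mv = 500, q_av = 0,
                           q_mv = 0, t = 0.45, T = T)
  expect_equal(st$mv, "open")
  # open AV closes on flow reversal
  st$av <- "open"
  st <- update_valve_state(st, dp_av = -10, dp_mv = 10, q_av = -10e-6,
                           q_mv = 1e-6, t = 0.50, T = T)
  expect_equal(st$av, "closed")
  # mid-diastolic mitral reversal must NOT close the MV (guard window)
  st <- update_valve_state(st, dp_av = -10, dp_mv = -5, q_av = 0,
                           q_mv = -10e-6, t = 0.55, T = T)
  expect_equal(st$mv, "open")
  # late-diastolic reversal does close it
  st <- update_valve_state(st, dp_av = -10, dp_mv = -5, q_av = 0,
                           q_mv = -10e-6, t = 0.78, T = T)
  expect_equal(st$mv, "closed")
  # the guard window wraps into early systole of the next cycle
  st$mv <- "open"
  st <- update_valve_state(st, dp_av = -10, dp_mv = -5, q_av = 0,
                           q_mv = -10e-6, t = T + 0.02, T = T)
  expect_equal(st$mv, "closed")
  # event log is ordered
  expect_true(all(diff(st$events$time) >= 0))
})

test_that("identical input sequences give identical event logs", {
  T <- 0.9
  seqs <- data.frame(
    t = seq(0.01, 2 * T, by = 0.01),
    dp_av = sin(seq(0.01, 2 * T, by = 0.01) * 7) * 2000,
    dp_mv = cos(seq(0.01, 2 * T, by = 0.01) * 5) * 1000,
    q_av = sin(seq(0.01, 2 * T, by = 0.01) * 9) * 1e-4,
    q_mv = cos(seq(0.01, 2 * T, by = 0.01) * 11) * 1e-4
  )
  play <- function() {
    st <- valve_state_init()
    for (i in seq_len(nrow(seqs))) {
      st <- update_valve_state(st, seqs$dp_av[i], seqs$dp_mv[i],
                               seqs$q_av[i], seqs$q_mv[i], seqs$t[i], T)
    }
    st$events
  }
  expect_identical(play(), play())
})

test_that("section flow rates integrate u.n exactly for linear fields", {
  # unit-area square section in the z plane, built from two triangles
  pts <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0.01, 0.01, 0), c(0, 0.01, 0))
  faces <- rbind(c(1, 2, 3), c(1, 3, 4)) # normal +z, area 1 cm^2
  u_uniform <- cbind(0, 0, rep(1, 4))
  expect_equal(valve_flow_rate(u_uniform, pts, faces), 1e-4)
  expect_equal(valve_flow_rate(-u_uniform, pts, faces), -1e-4)
  expect_equal(valve_flow_rate(u_uniform, pts, faces, orientation = -1),
               -1e-4)
  expect_error(valve_flow_rate(u_uniform, pts, NULL), "section")
  # parabolic profile over a circular orifice: Q = U pi a^2 / 2, on a
  # finely triangulated full disc section
  a <- 0.009
  disc <- lhflow:::.disc_surface(c(0, 0, 0), a, 0, 48L)
  rr2 <- disc$points[, 1]^2 + disc$points[, 2]^2
  U <- 0.8
  u_par <- cbind(0, 0, U * pmax(1 - rr2 / a^2, 0))
  q <- valve_flow_rate(u_par, disc$points, disc$tris)
  expect_lt(abs(q - U * pi * a^2 / 2) / (U * pi * a^2 / 2), 0.03)
})

test_that("closed valve seals under a transvalvular load, monotone in R", {
  # static tube with a closed resistive disc in the middle, 20 mmHg drop
  fix <- tube_fixture()
  m <- fix$mesh
  eps <- 1.2 * m$h
  mkdisc <- function() {
    # a disc valve sealing the tube mid-plane
    s <- lhflow:::.disc_surface(c(0, 0, fix$length / 2), fix$radius, 0, 28L)
    structure(c(s, list(kind = "mitral", configuration = "closed",
                        eps_gamma = eps, r_gamma = 1e5)),
              class = "valve_surface")
  }
  v <- mkdisc()
  dp <- lhflow::mmHg_to_Pa(20)
  # the raised test viscosity keeps the 20 mmHg open-valve jet at a
  # physiological few m/s and the steady state quick to reach
  q_open <- valve_flow_rate(
    run_tube(dp, mu = 0.15, nstep = 180, dt = 1.5e-4)$state$u,
    m$points, m$faces[fix$labels == "outlet", , drop = FALSE])
  leak <- vapply(c(1e3, 1e4, 1e5), function(R) {
    rd <- (R / eps) * riis_delta(m$points, v, eps_gamma = eps)
    st <- run_tube(dp, mu = 0.15, nstep = 180, dt = 1.5e-4,
                   riis_diag = rd)$state
    abs(valve_flow_rate(st$u, m$points,
                        m$faces[fix$labels == "outlet", , drop = FALSE]))
  }, numeric(1))
  # leakage decreases monotonically with the resistance
  expect_true(all(diff(leak) < 0))
  # and at the working resistance it is < 2% of the open-valve flow
  expect_lt(leak[3] / abs(q_open), 0.02)
})

test_that("valves move with the domain and stay attached to the annulus", {
  g <- heart_geom_h()
  v <- valve_surface(g, "mitral", "closed")
  # zero motion: identical surface
  v0 <- move_valve_with_domain(v, function(p) 0 * p)
  expect_equal(v0$points, v$points)
  # rigid translation: valve translates rigidly
  cvec <- c(1e-3, -2e-3, 3e-3)
  v1 <- move_valve_with_domain(v, function(p) {
    matrix(rep(cvec, each = nrow(p)), ncol = 3)
  })
  expect_equal(v1$points, v$points + rep(cvec, each = nrow(v$points)))
  # over a generic cycle the annulus stays on the (static) channel wall:
  # the prescribed motion vanishes on the orifice structures
  mo <- heart_motion_h()
  for (fr in c(1L, 8L, 16L, 25L)) {
    d_ann <- mo$disp_at(v$points[v$annulus_idx, , drop = FALSE], fr)
    expect_lt(max(abs(d_ann)), 0.1 * v$eps_gamma)
  }
})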