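# Wall shear stress indices, bulk flow metrics, and the clinical helper
# arithmetic.

test_that("WSS recovers a linear shear and vanishes for rigid motion", {
  # small box mesh with an imposed linear shear u = (gdot*z, 0, 0); the
  # bottom face (z = 0) is the wall: |WSS| = mu * gdot
  box <- imp_cylinder_z(c(0, 0), 0.02, 0, 0.008)
  m <- voxel_tet_mesh(box, rbind(c(-0.024, -0.024, -0.004),
                                 c(0.024, 0.024, 0.012)), 2e-3)
  fg <- face_geometry(m$points, m$faces)
  bottom <- abs(fg$centroid[, 3]) < 1e-6 &
    sqrt(fg$centroid[, 1]^2 + fg$centroid[, 2]^2) < 0.015
  faces <- m$faces[bottom, , drop = FALSE]
  owners <- lhflow:::wall_face_tets(m)[bottom]
  gdot <- 100; mu <- 3.5e-3
  u <- cbind(gdot * m$points[, 3], 0, 0)
  wss <- wall_shear_stress(u, m$points, m, faces, owners, mu)
  expect_equal(mean(sqrt(rowSums(wss^2))), mu * gdot, tolerance = 1e-6)
  # rigid rotation of fluid and wall together: symmetric gradient is zero
  om <- c(0, 0, 12)
  u_rot <- cbind(-om[3] * m$points[, 2], om[3] * m$points[, 1], 0)
  wss0 <- wall_shear_stress(u_rot, m$points, m, faces, owners, mu)
  expect_lt(max(abs(wss0)), 1e-9)
})

test_that("TAWSS, OSI and RRT closed forms", {
  f <- 4L # faces
  m <- 8L # phases
  w <- 0.2
  # constant magnitude w -> TAWSS = w, OSI = 0, RRT = 1/w
  wss_const <- array(0, c(f, 3, m)); wss_const[, 1, ] <- w
  expect_equal(tawss(wss_const), rep(w, f))
  expect_equal(osi(wss_const), rep(0, f))
  expect_equal(rrt(tawss(wss_const), osi(wss_const)), rep(1 / w, f))
  # w for half cycle, 0 for half -> TAWSS = w/2
  wss_half <- array(0, c(f, 3, m)); wss_half[, 1, 1:4] <- w
  expect_equal(tawss(wss_half), rep(w / 2, f))
  # perfectly reversing shear -> OSI = 0.5, RRT infinite
  wss_rev <- array(0, c(f, 3, m))
  wss_rev[, 1, 1:4] <- w; wss_rev[, 1, 5:8] <- -w
  expect_equal(osi(wss_rev), rep(0.5, f))
  expect_true(all(is.infinite(rrt(tawss(wss_rev), osi(wss_rev)))))
  # +w for 3/4 cycle, -w for 1/4 -> OSI = 0.25; with TAWSS = 1: RRT = 2
  wss_34 <- array(0, c(1, 3, m))
  wss_34[, 1, 1:6] <- w; wss_34[, 1, 7:8] <- -w
  expect_equal(osi(wss_34), 0.25)
  expect_equal(rrt(1, 0.25), 2)
  expect_equal(rrt(0.2, 0), 5)
  # sampled |sin| over a period averages to 2w/pi
  ph <- (seq_len(64L) - 0.5) / 64
  wss_sin <- array(0, c(1, 3, 64L)); wss_sin[1, 1, ] <- w * sin(pi * ph)
  expect_equal(tawss(wss_sin), 2 * w / pi, tolerance = 1e-3)
})

test_that("area fractions above a threshold count area, not faces", {
  field <- c(10, 1, 10, 1)
  areas <- c(1, 1, 2, 2) * 1e-6
  expect_equal(area_fraction_above(field, 5, areas), 50)
  expect_equal(area_fraction_above(field, 0, areas), 100)
  expect_equal(area_fraction_above(field, 100, areas), 0)
  expect_equal(area_fraction_above(field, 5, areas, c(TRUE, TRUE, FALSE, FALSE)),
               50)
  expect_error(area_fraction_above(field, 5, areas, rep(FALSE, 4)), "empty")
})

test_that("E-wave propagation index closed forms", {
  A <- 4e-4 # orifice area
  # constant mean velocity 0.5 m/s for 0.2 s, L = 0.1 m -> EPI = 1
  t <- seq(0, 0.4, by = 1e-3)
  q <- ifelse(t > 0.1 & t <= 0.3, 0.5 * A, 0)
  e1 <- epi(q, t, A, 0.1, t_av_close = 0.05)
  expect_equal(as.numeric(e1), 1.0, tolerance = 0.02)
  # doubled velocity doubles EPI
  e2 <- epi(2 * q, t, A, 0.1, t_av_close = 0.05)
  expect_equal(as.numeric(e2), 2 * as.numeric(e1), tolerance = 1e-9)
  # triangular lobe: peak 1 m/s, base 0.2 s -> distance 0.1 m; L = 0.05
  qt <- A * pmax(0, 1 - abs(t - 0.2) / 0.1)
  e3 <- epi(qt, t, A, 0.05, t_av_close = 0.05)
  expect_equal(as.numeric(e3), 2.0, tolerance = 0.05)
  expect_error(epi(-q, t, A, 0.1), "forward")
})

test_that("probe pressures average the field over the sphere", {
  g <- heart_geom_h()
  m <- g$mesh
  # uniform field
  expect_equal(pressure_probe(rep(7, nrow(m$points)), m$points, m$tets,
                              g$probes$LV$center, g$probes$LV$radius), 7)
  # linear field: volume average over the sphere equals the center value
  pc <- g$probes$LA$center
  p_lin <- 100 + 2000 * (m$points[, 1] - pc[1]) - 500 * (m$points[, 3] - pc[3])
  expect_equal(pressure_probe(p_lin, m$points, m$tets, pc, g$probes$LA$radius),
               100, tolerance = 0.05 * 2000 * g$probes$LA$radius)
  expect_error(pressure_probe(p_lin, m$points, m$tets, c(1, 1, 1), 0.001),
               "intersect")
})

test_that("clinical helper arithmetic reproduces the reference values", {
  vit <- lh_reference_vitals()
  expect_equal(bsa_du_bois(vit$height_m, vit$weight_kg),
               vit$bsa_reported_m2) # 2.14, 2.28
  expect_equal(bsa_du_bois(1.80, 75), 1.94)
  expect_equal(heartbeat_period(vit$heart_rate_bpm), vit$period_s) # 0.9, 0.8
  expect_equal(heartbeat_period(60), 1.0)
  ecd <- lh_reference_ecd()
  expect_equal(relative_discrepancy(ecd$ecd_m_s, ecd$sim_m_s),
               ecd$delta_reported_pct) # 4.0, 5.9, 3.2
  expect_equal(relative_discrepancy(2, 2), 0)
  expect_equal(phase_fraction(0.32, 0.8), 40)
  expect_equal(phase_fraction(0.77, 0.8), 96)
  expect_equal(phase_fraction(0, 0.9), 0)
  expect_error(bsa_du_bois(-1, 70), "positive")
  expect_error(heartbeat_period(0), "positive")
  expect_error(relative_discrepancy(0, 1), "zero")
  expect_error(phase_fraction(1.0, 0.8), "outside")
})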