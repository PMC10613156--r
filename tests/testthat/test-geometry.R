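# Idealized left-heart anatomy: labels, volumes, valve sealing geometry,
# and the matched-topology contract between scenarios.

test_that("healthy anatomy satisfies the labelling and volume contracts", {
  g <- heart_geom_h()
  # regions partition the cells
  expect_true(all(g$cell_region %in% 1:3))
  # apex cells are LV cells, appendage cells are LA cells
  expect_true(all(g$cell_region[g$apex_cells] == 1L))
  expect_true(all(g$cell_region[g$laa_cells] == 2L))
  # enclosed LV volume within 1% of the analytic generating solid
  expect_lt(abs(g$reference_volume_LV - g$lv_analytic_volume) /
              g$lv_analytic_volume, 0.01)
  # face labels partition the boundary
  expect_true(all(g$face_label %in%
                    c("LV", "LV_apex", "LA", "LAA", "AR",
                      "PV_inlet", "AR_outlet")))
  # open patches exist and have interior nodes
  expect_gt(length(g$inlet_nodes), 0)
  expect_gt(length(g$outlet_nodes), 0)
  # annulus curves sit between the chamber regions: the mitral annulus plane
  # separates LV-labelled from LA-labelled channel cells
  cen <- tet_centroids(g$mesh)
  in_ch <- sqrt((cen[, 1] - g$shape$mv_center_x)^2 + cen[, 2]^2) <
    g$shape$mv_radius & cen[, 3] > g$dims$zb &
    cen[, 3] < g$dims$zb + g$shape$mv_channel_len
  expect_true(all(g$cell_region[in_ch & cen[, 3] < g$z_mv] == 1L))
  expect_true(all(g$cell_region[in_ch & cen[, 3] > g$z_mv] == 2L))
  expect_equal(unique(g$mitral_annulus[, 3]), g$z_mv)
})

test_that("healthy and regurgitant geometries share the mesh topology", {
  g_h <- heart_geom_h()
  g_r <- fixture("geom_r", function() {
    generate_anatomy(lh_scenario("regurgitant"))
  })
  expect_identical(g_h$mesh$tets, g_r$mesh$tets)
  expect_identical(g_h$cell_region, g_r$cell_region)
  # the dilated ventricle hits its target end-systolic volume
  pr <- g_r$params
  expect_lt(abs(g_r$reference_volume_LV -
                  pr$edv * (1 - pr$ejection_fraction)) /
              (pr$edv * (1 - pr$ejection_fraction)), 0.01)
  # dilation factor on linear dimensions is about 1.25
  expect_equal(unname(1 + g_r$dilation["lv"]),
               (g_r$reference_volume_LV / g_h$reference_volume_LV)^(1 / 3),
               tolerance = 0.05)
})

test_that("closed mitral leaflet seals the annulus or carries the orifice", {
  g <- heart_geom_h()
  sealed <- valve_surface(g, "mitral", "closed")
  # healthy closed configuration: no hole, surface area = full disc
  a_disc <- pi * g$shape$mv_radius^2
  fg <- face_geometry(sealed$points, sealed$tris)
  expect_lt(abs(sum(fg$area) - a_disc) / a_disc, 0.02)

  g_r <- fixture("geom_r", function() {
    generate_anatomy(lh_scenario("regurgitant"))
  })
  roa <- g_r$params$regurgitant_orifice_area
  gap <- valve_surface(g_r, "mitral", "closed")
  fg2 <- face_geometry(gap$points, gap$tris)
  hole <- a_disc - sum(fg2$area)
  expect_lt(abs(hole - roa) / roa, 0.05)
})

test_that("degenerate scenario parameters are rejected", {
  expect_error(lh_scenario("healthy", ejection_fraction = 1.2))
  expect_error(lh_scenario("healthy", edv = -1))
  expect_error(lh_scenario("healthy", nonsense = 1), "unknown")
})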