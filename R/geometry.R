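# Synthetic left-heart anatomy.
#
# The idealized chamber assembly is: a truncated prolate ellipsoid for the
# left ventricle (long axis along z, apex down, truncated by the base plane
# z = zb), a short cylindrical mitral channel and a cylindrical aortic root
# rising from the base plane, an oblate-ellipsoid left atrium above the
# mitral channel with a small spherical appendage pouch, and two cylindrical
# pulmonary-vein stubs on top of the atrium whose flat caps are the inlet
# patches. The aortic-root cap is the outlet patch. Everything is meshed as
# one implicit union.

#' Scenario parameters for a left-heart simulation
#'
#' Bundles the physiological parameters of a simulated subject. The two named
#' presets approximate a healthy subject (66 bpm, no regurgitant orifice,
#' constant 10 mmHg venous pressure) and a subject with severe mitral
#' regurgitation (75 bpm, dilated chambers, a 0.4 cm^2 regurgitant orifice in
#' the closed mitral leaflet, venous pressure rising to 40 mmHg in systole).
#' The heartbeat period is `round(60/heart_rate, 1)` seconds, the rounding
#' convention used for reporting.
#'
#' @param scenario `"healthy"`, `"regurgitant"` or `"custom"`.
#' @param heart_rate beats per minute.
#' @param ejection_fraction LV ejection fraction, in (0, 1).
#' @param edv LV end-diastolic volume, m^3.
#' @param regurgitant_orifice_area area of the hole in the closed mitral
#'   leaflet, m^2 (0 = competent valve).
#' @param n_frames wall-motion frames per heartbeat (cine acquisition rate).
#' @param t_es_frac end-systolic instant as a fraction of the cycle; snapped
#'   to the frame grid so the reference frame has exactly zero displacement.
#' @param la_ef left-atrial total emptying fraction of the reservoir volume.
#' @param la_volume_ratio LA reference (end-systolic) volume / LV ESV.
#' @param venous_pressure_profile `"constant"` or `"elevated"` (systolic rise).
#' @param venous_peak peak venous pressure for the elevated profile, Pa.
#' @param aortic_pressure_profile id of the aortic waveform (only
#'   `"physiological"` is provided).
#' @param n_cycles simulated heartbeats.
#' @param discard_cycles initial heartbeats excluded from statistics.
#' @param perturbation_seed integer seed for the per-cycle inflow
#'   perturbations.
#' @param perturbation_frac perturbation amplitude as a fraction of the peak
#'   mitral inflow speed.
#' @param dt solver time step, s.
#' @param ... overrides any of the above.
#' @return an object of class `lh_scenario`.
#' @examples
#' p <- lh_scenario("healthy")
#' p$period_T # 0.9
#' @export
lh_scenario <- function(scenario = c("healthy", "regurgitant", "custom"), ...) {
  scenario <- match.arg(scenario)
  base <- list(
    name = scenario,
    heart_rate = 66,
    ejection_fraction = 0.58,
    edv = 130e-6,
    regurgitant_orifice_area = 0,
    n_frames = 30L,
    t_es_frac = 10 / 30,
    la_ef = 0.40,
    la_volume_ratio = 1.1,
    venous_pressure_profile = "constant",
    venous_pressure = mmHg_to_Pa(10),
    venous_peak = mmHg_to_Pa(40),
    aortic_pressure_profile = "physiological",
    n_cycles = 3L,
    discard_cycles = 1L,
    perturbation_seed = 20260101L,
    perturbation_frac = 0.01,
    dt = 5e-4
  )
  if (scenario == "regurgitant") {
    base$heart_rate <- 75
    base$edv <- 250e-6
    base$regurgitant_orifice_area <- 0.4e-4
    base$t_es_frac <- 12 / 30
    base$la_ef <- 0.45
    base$venous_pressure_profile <- "elevated"
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown)) stop("unknown scenario parameters: ",
                            paste(unknown, collapse = ", "))
  base[names(ov)] <- ov
  base$period_T <- round(60 / base$heart_rate, 1)
  # snap end systole to the frame grid
  base$t_es_frac <- round(base$t_es_frac * base$n_frames) / base$n_frames
  p <- structure(base, class = "lh_scenario")
  validate_scenario(p)
  p
}

#' @keywords internal
validate_scenario <- function(p) {
  stopifnot(
    p$heart_rate > 0,
    abs(p$period_T - round(60 / p$heart_rate, 1)) < 1e-12,
    p$ejection_fraction > 0, p$ejection_fraction < 1,
    p$regurgitant_orifice_area >= 0,
    p$edv > 0, p$n_frames >= 4,
    p$n_cycles >= p$discard_cycles + 1,
    p$dt > 0
  )
  invisible(p)
}

#' Shape controls for the idealized anatomy
#'
#' Geometric proportions of the synthetic left heart. Absolute chamber sizes
#' derive from the scenario's end-systolic volume; the controls below fix the
#' proportions and orifice sizes (m where dimensional).
#'
#' @param lv_aspect LV long semi-axis / short semi-axis.
#' @param lv_trunc_frac base-plane height as a fraction of the long semi-axis.
#' @param mv_radius,mv_center_x mitral channel radius and x offset.
#' @param mv_channel_len axial length of the mitral channel above the base.
#' @param ar_radius,ar_center_x,ar_height aortic-root radius, x offset and
#'   cap height above the base plane.
#' @param ar_tilt tilt of the aortic root axis away from z (radians, in the
#'   x-z plane) so the root clears the atrium; its cap stays horizontal.
#' @param av_offset height of the aortic annulus above the base plane.
#' @param la_center_x x offset of the LA axis.
#' @param la_aspect_y,la_aspect_z LA semi-axis ratios a_y/a_x and c/a_x; the
#'   atrium is elongated along y so it clears the tilted aortic root in x.
#' @param la_bottom_gap clearance between the atrial floor and the
#'   ventricular base plane (the chambers must communicate only through the
#'   mitral channel, which pokes through this gap into the atrium).
#' @param laa_radius appendage pouch radius.
#' @param pv_radius,pv_offset_y,pv_height pulmonary-vein stub radius, y
#'   offsets from the LA axis (+/-), and cap height above the LA apex.
#' @param base_esv LV end-systolic volume of the undilated template, m^3. All
#'   scenarios share the template mesh topology; scenarios with a different
#'   ESV reach it through a smooth calibrated chamber dilation so healthy and
#'   regurgitant meshes stay vertex-matched.
#' @param taper_len length scale over which wall motion fades to zero near
#'   the (static) orifices, annuli and open boundaries, m.
#' @param max_disp_frac bound on motion amplitude (fraction of local radius).
#' @param mesh_h target mesh spacing, m.
#' @param cull_ef,cull_la_ef,cull_esv_max worst-case ejection fraction,
#'   atrial emptying fraction and end-systolic volume covered by the
#'   scenario-independent motion-robustness culling; scenarios within these
#'   bounds built from the same template share the mesh topology.
#' @return a list of class `lh_shape`.
#' @export
lh_shape_controls <- function(lv_aspect = 2.0,
                              lv_trunc_frac = 0.30,
                              mv_radius = 0.009,
                              mv_center_x = -0.0095,
                              mv_channel_len = 0.012,
                              ar_radius = 0.0075,
                              ar_center_x = 0.0115,
                              ar_height = 0.018,
                              ar_tilt = 20 * pi / 180,
                              av_offset = 0.004,
                              la_center_x = -0.014,
                              la_aspect_y = 2.2,
                              la_aspect_z = 1.25,
                              la_bottom_gap = 0.0045,
                              laa_radius = 0.008,
                              pv_radius = 0.006,
                              pv_offset_y = 0.016,
                              pv_height = 0.005,
                              base_esv = 130e-6 * (1 - 0.58),
                              taper_len = 0.014,
                              max_disp_frac = 0.85,
                              mesh_h = 0.0035,
                              cull_ef = 0.58,
                              cull_la_ef = 0.45,
                              cull_esv_max = 250e-6 * (1 - 0.58)) {
  ctl <- as.list(environment())
  if (lv_aspect <= 0 || mv_radius <= 0 || ar_radius <= 0 ||
      la_aspect_y <= 0 || la_aspect_z <= 0 || base_esv <= 0 || mesh_h <= 0) {
    stop("degenerate shape controls: semi-axes, radii and volumes must be > 0")
  }
  structure(ctl, class = "lh_shape")
}

# truncated-ellipsoid volume below z = t*c (t in (-1, 1)), semi-axes a, a, c
#' @keywords internal
ellipsoid_cap_volume <- function(a, c, t) {
  pi * a^2 * c * (2 / 3 + t - t^3 / 3)
}

#' @keywords internal
lh_dimensions <- function(params, shape) {
  t <- shape$lv_trunc_frac
  fac <- 2 / 3 + t - t^3 / 3
  a <- (shape$base_esv / (pi * shape$lv_aspect * fac))^(1 / 3)
  c <- shape$lv_aspect * a
  zb <- t * c
  v_la <- params$la_volume_ratio * shape$base_esv
  a_la <- (3 * v_la /
             (4 * pi * shape$la_aspect_y * shape$la_aspect_z))^(1 / 3)
  b_la <- shape$la_aspect_y * a_la # long horizontal semi-axis, along y
  c_la <- shape$la_aspect_z * a_la
  la_center <- c(shape$la_center_x, 0, zb + shape$la_bottom_gap + c_la)
  list(
    a = a, c = c, zb = zb,
    a_la = a_la, b_la = b_la, c_la = c_la, la_center = la_center,
    z_ar_top = zb + shape$ar_height,
    z_pv_top = la_center[3] + c_la + shape$pv_height,
    laa_center = c(la_center[1], -(b_la + shape$laa_radius - 0.005),
                   la_center[3])
  )
}

#' Generate the idealized left-heart geometry
#'
#' Builds the labelled tetrahedral mesh of the idealized left heart at the
#' end-systolic reference configuration. The mesh topology is generated once
#' from the template shape in `shape`; if the scenario's end-systolic volume
#' differs from the template's (e.g. the dilated regurgitant subject), the
#' vertices are displaced by a smooth, calibrated chamber dilation so that
#' every scenario shares the same mesh topology and downstream comparisons
#' are vertex-matched.
#'
#' @param params an [lh_scenario()].
#' @param shape an [lh_shape_controls()].
#' @param mesh_h optional mesh spacing override, m.
#' @return an object of class `lh_geometry`: the `tet_mesh`, per-cell region
#'   labels (`LV`, `LA`, `AR` plus `apex_cells`/`laa_cells` masks), labelled
#'   boundary faces, node sets for the wall and the open boundaries, the
#'   mitral/aortic annulus curves, internal flux sections through both
#'   orifices, pressure-probe spheres, reference chamber volumes and the LV
#'   long-axis length.
#' @export
generate_anatomy <- function(params, shape = lh_shape_controls(),
                             mesh_h = NULL) {
  stopifnot(inherits(params, "lh_scenario"), inherits(shape, "lh_shape"))
  h <- if (is.null(mesh_h)) shape$mesh_h else mesh_h
  dm <- lh_dimensions(params, shape)

  # snap the open-boundary cap planes to the mesh grid so the inlet/outlet
  # patches come out flat and identifiable
  z_lo <- -dm$c - 2.5 * h
  grid_zs <- seq(z_lo, dm$z_pv_top + 5 * h, by = h)
  dm$z_ar_top <- grid_zs[which.min(abs(grid_zs - dm$z_ar_top))]
  dm$z_pv_top <- grid_zs[which.min(abs(grid_zs - dm$z_pv_top))]

  lv_solid <- imp_intersect(
    imp_ellipsoid(c(0, 0, 0), c(dm$a, dm$a, dm$c)),
    imp_halfspace_z(dm$zb)
  )
  mv_channel <- imp_cylinder_z(c(shape$mv_center_x, 0), shape$mv_radius,
                               dm$zb - 0.75 * h, dm$zb + shape$mv_channel_len)
  ar_cyl <- imp_cylinder_tilted(c(shape$ar_center_x, 0), shape$ar_radius,
                                dm$zb - 0.75 * h, dm$z_ar_top, shape$ar_tilt)
  la_solid <- imp_ellipsoid(dm$la_center, c(dm$a_la, dm$b_la, dm$c_la))
  laa_solid <- imp_sphere(dm$laa_center, shape$laa_radius)
  pv1 <- imp_cylinder_z(dm$la_center[1:2] + c(0, shape$pv_offset_y),
                        shape$pv_radius, dm$la_center[3], dm$z_pv_top)
  pv2 <- imp_cylinder_z(dm$la_center[1:2] + c(0, -shape$pv_offset_y),
                        shape$pv_radius, dm$la_center[3], dm$z_pv_top)
  solid <- imp_union(lv_solid, mv_channel, ar_cyl, la_solid, laa_solid,
                     pv1, pv2)

  # fit checks: orifices inside the LV base rim, atrium clear of the root
  rim <- dm$a * sqrt(max(0, 1 - (dm$zb / dm$c)^2))
  ar_semi_x <- shape$ar_radius / cos(shape$ar_tilt)
  if (abs(shape$mv_center_x) + shape$mv_radius >= rim ||
      abs(shape$ar_center_x) + ar_semi_x >= rim) {
    stop("orifices do not fit inside the LV base: reduce radii or offsets")
  }
  # the mitral channel must reach well into the atrium through the floor gap
  la_floor_at_channel <- dm$la_center[3] - dm$c_la *
    sqrt(max(0, 1 - ((shape$mv_center_x - dm$la_center[1]) / dm$a_la)^2))
  if (dm$zb + shape$mv_channel_len < la_floor_at_channel + 1.5 * h) {
    stop("mitral channel does not reach the atrium; lengthen ",
         "mv_channel_len or reduce la_bottom_gap")
  }
  if (shape$la_bottom_gap < 1.1 * h) {
    stop("la_bottom_gap below the mesh spacing: chambers would fuse ",
         "outside the mitral channel")
  }
  zz <- seq(dm$la_center[3] - dm$c_la, dm$la_center[3] + dm$c_la,
            length.out = 41)
  la_xmax <- dm$la_center[1] +
    dm$a_la * sqrt(pmax(0, 1 - ((zz - dm$la_center[3]) / dm$c_la)^2))
  ar_xmin <- shape$ar_center_x + tan(shape$ar_tilt) * (zz - dm$zb) - ar_semi_x
  if (any(zz <= dm$z_ar_top & la_xmax > ar_xmin - h)) {
    stop("atrium intersects or nearly touches the aortic root; ",
         "increase ar_tilt / ar_center_x or shrink the atrium in x")
  }

  pad <- 2.5 * h
  bbox <- rbind(
    c(min(-dm$a, dm$la_center[1] - dm$a_la) - pad,
      dm$laa_center[2] - shape$laa_radius - pad,
      z_lo),
    c(max(dm$a, shape$ar_center_x + tan(shape$ar_tilt) * shape$ar_height +
            ar_semi_x, dm$la_center[1] + dm$a_la) + pad,
      max(dm$a, dm$la_center[2] + dm$b_la) + pad,
      dm$z_pv_top + 2.5 * h)
  )
  mesh <- voxel_tet_mesh(solid, bbox, h)
  # smooth everywhere except near the static orifice/root/vein structures,
  # whose interior vertices must stay on grid planes for the flux sections
  static_dist <- function(pts) {
    pmin(mv_channel(pts), ar_cyl(pts), pv1(pts), pv2(pts))
  }
  frozen <- which(static_dist(mesh$points) < 2 * h)
  mesh <- smooth_tet_mesh(mesh, solid, h, fixed = frozen)

  # section planes snapped to the grid so region interfaces are flat
  snap <- function(z_target, lo) {
    cand <- grid_zs[grid_zs > lo + 0.25 * h]
    cand[which.min(abs(cand - z_target))]
  }
  z_mv <- snap(dm$zb + shape$mv_channel_len / 2, dm$zb)
  z_av <- snap(dm$zb + shape$av_offset, dm$zb)

  classify_cells <- function(mesh) {
    cen <- tet_centroids(mesh)
    z <- cen[, 3]
    region <- rep(NA_integer_, nrow(cen)) # 1 LV, 2 LA, 3 AR
    region[la_solid(cen) < 0 | laa_solid(cen) < 0 | pv1(cen) < 0 |
             pv2(cen) < 0 | (mv_channel(cen) < 0 & z >= z_mv)] <- 2L
    region[ar_cyl(cen) < 0 & z >= z_av] <- 3L
    region[lv_solid(cen) < 0 | (mv_channel(cen) < 0 & z < z_mv) |
             (ar_cyl(cen) < 0 & z < z_av)] <- 1L
    region[is.na(region)] <- ifelse(z[is.na(region)] < dm$zb, 1L, 2L)
    region
  }

  # Motion-robustness culling, SCENARIO-INDEPENDENT so every scenario built
  # from the same shape template drops the same cells and the meshes stay
  # vertex-matched. Fragile cells are those that would invert anywhere in a
  # worst-case amplitude box (covering both presets, with margins), checked
  # through the actual runtime mesh motion -- the elastic extension of the
  # boundary displacement basis -- at both the template and the maximally
  # dilated reference configurations.
  pseudo <- list(dims = dm, static_dist = static_dist, shape = shape)
  esv_target <- params$edv * (1 - params$ejection_fraction)
  lv_box <- c(-0.10, (1 / (1 - shape$cull_ef))^(1 / 3) - 1 + 0.12)
  la_box <- c((1 - shape$cull_la_ef)^(1 / 3) - 1 - 0.12, 0.10)
  dil_needed_max <- shape$cull_esv_max / shape$base_esv > 1 + 1e-6
  for (it in 1:6) {
    region0 <- classify_cells(mesh)
    # analytic pre-pass (cheap) on the template coordinates; the upper
    # corners are extended by the maximal dilation amplitudes so the
    # dilated configuration below is approximately covered too
    dil_amt <- max(0, (shape$cull_esv_max / shape$base_esv)^(1 / 3) - 1)
    bs <- motion_basis(pseudo, mesh$points)
    vmin <- rep(Inf, nrow(mesh$tets))
    for (alv in seq(lv_box[1], lv_box[2] + dil_amt, length.out = 6)) {
      for (ala in seq(la_box[1], la_box[2] + dil_amt, length.out = 6)) {
        vmin <- pmin(vmin, tet_geom_cpp(
          mesh$points + alv * bs$g_lv + ala * bs$g_la, mesh$tets)$vol)
      }
    }
    fragile <- vmin < 0.008 * h^3 / 6
    # extension-based pass at the template and max-dilated configurations
    cfgs <- list(mesh$points)
    if (dil_needed_max) {
      resx <- .dilate_mesh(mesh, region0, pseudo, shape$cull_esv_max,
                           params$la_volume_ratio * shape$cull_esv_max)
      cfgs <- c(cfgs, list(resx$points))
    }
    for (pts_ref in cfgs) {
      bad0 <- tet_geom_cpp(pts_ref, mesh$tets)$vol < 0.006 * h^3 / 6
      if (any(bad0)) {
        # configuration itself invalid: cull and retry before building the
        # extension operator on it
        fragile <- fragile | bad0
        next
      }
      meshd <- mesh
      meshd$points <- pts_ref
      ext <- extension_operator(meshd)
      bnodes <- meshd$boundary_vertices
      bb <- motion_basis(pseudo, pts_ref[bnodes, , drop = FALSE])
      for (alv in seq(lv_box[1], lv_box[2], length.out = 5)) {
        for (ala in seq(la_box[1], la_box[2], length.out = 5)) {
          full <- extend_displacement(ext, alv * bb$g_lv + ala * bb$g_la)
          fragile <- fragile |
            (tet_geom_cpp(pts_ref + full, meshd$tets)$vol < 0.006 * h^3 / 6)
        }
      }
    }
    if (!any(fragile)) break
    if (it == 6L) stop("could not build a motion-safe mesh template")
    mesh <- .drop_cells(mesh, !fragile)
  }

  # Dilate to this scenario's end-systolic volume (points only; topology
  # untouched) and verify the actual calibrated motion stays valid. All
  # membership-based annotation below uses the template coordinates, so the
  # dilated points are swapped in only at the very end.
  dilation <- NULL
  pts_final <- NULL
  region0 <- classify_cells(mesh)
  if (abs(esv_target - shape$base_esv) / shape$base_esv > 1e-6) {
    if (esv_target > shape$cull_esv_max * (1 + 1e-9)) {
      stop("scenario end-systolic volume exceeds cull_esv_max; raise it in ",
           "lh_shape_controls so the template is culled for this dilation")
    }
    res <- .dilate_mesh(mesh, region0, pseudo, esv_target,
                        params$la_volume_ratio * esv_target)
    pts_final <- res$points
    dilation <- res$betas
  }
  {
    pts_ref <- if (is.null(pts_final)) mesh$points else pts_final
    meshd <- mesh
    meshd$points <- pts_ref
    amp <- motion_amplitudes(meshd, region0, pseudo, params)
    ext <- extension_operator(meshd)
    bb <- motion_basis(pseudo, pts_ref[meshd$boundary_vertices, ,
                                       drop = FALSE])
    asp <- periodic_spline(cbind(amp$amp_lv, amp$amp_la), params$period_T)
    tchk <- (seq_len(2L * params$n_frames) - 1) * params$period_T /
      (2L * params$n_frames)
    for (t in tchk) {
      a <- eval_periodic_spline(asp, t)
      full <- extend_displacement(ext, a[1] * bb$g_lv + a[2] * bb$g_la)
      if (any(tet_geom_cpp(pts_ref + full, meshd$tets)$vol <= 0)) {
        stop("mesh motion would tangle at phase ", round(t / params$period_T, 3),
             "; widen the cull amplitude box (cull_ef / cull_la_ef)")
      }
    }
  }

  region <- classify_cells(mesh)
  cen <- tet_centroids(mesh)
  z <- cen[, 3]
  in_laa <- laa_solid(cen) < 0
  lv_axial_len <- dm$zb + dm$c
  z_apex <- -dm$c + 0.30 * lv_axial_len
  apex_cells <- region == 1L & z < z_apex
  laa_cells <- region == 2L & in_laa

  # boundary face labels
  fg <- face_geometry(mesh$points, mesh$faces)
  fc <- fg$centroid
  lab <- rep("wall", nrow(fc))
  ar_cap_c <- c(shape$ar_center_x + tan(shape$ar_tilt) * (dm$z_ar_top - dm$zb),
                0)
  is_out <- abs(fc[, 3] - dm$z_ar_top) < 0.3 * h &
    sqrt(((fc[, 1] - ar_cap_c[1]) / (ar_semi_x / shape$ar_radius))^2 +
           fc[, 2]^2) < shape$ar_radius + 0.5 * h
  pvc1 <- dm$la_center[1:2] + c(0, shape$pv_offset_y)
  pvc2 <- dm$la_center[1:2] + c(0, -shape$pv_offset_y)
  is_in1 <- abs(fc[, 3] - dm$z_pv_top) < 0.3 * h &
    sqrt((fc[, 1] - pvc1[1])^2 + (fc[, 2] - pvc1[2])^2) < shape$pv_radius + 0.5 * h
  is_in2 <- abs(fc[, 3] - dm$z_pv_top) < 0.3 * h &
    sqrt((fc[, 1] - pvc2[1])^2 + (fc[, 2] - pvc2[2])^2) < shape$pv_radius + 0.5 * h
  lab[is_out] <- "AR_outlet"
  lab[is_in1 | is_in2] <- "PV_inlet"

  wall_region <- rep(NA_character_, nrow(fc))
  wz <- fc[, 3]
  w_la <- la_solid(fc) < 0.5 * h | pv1(fc) < 0.5 * h | pv2(fc) < 0.5 * h |
    (mv_channel(fc) < 0.5 * h & wz >= z_mv)
  w_laa <- laa_solid(fc) < 0.5 * h
  w_ar <- ar_cyl(fc) < 0.5 * h & wz >= z_av
  wall_region[w_la] <- "LA"
  wall_region[w_laa] <- "LAA"
  wall_region[w_ar] <- "AR"
  w_lv <- is.na(wall_region)
  wall_region[w_lv] <- ifelse(fc[w_lv, 3] < z_apex, "LV_apex", "LV")
  face_label <- ifelse(lab == "wall", wall_region, lab)

  # node sets: rim nodes shared by wall and an open patch count as wall
  open_face_nodes <- unique(as.vector(mesh$faces[lab != "wall", , drop = FALSE]))
  wall_nodes <- unique(as.vector(mesh$faces[lab == "wall", , drop = FALSE]))
  open_nodes <- setdiff(open_face_nodes, wall_nodes)
  inlet_nodes <- setdiff(
    unique(as.vector(mesh$faces[lab == "PV_inlet", , drop = FALSE])), wall_nodes)
  outlet_nodes <- setdiff(
    unique(as.vector(mesh$faces[lab == "AR_outlet", , drop = FALSE])), wall_nodes)

  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  mitral_annulus <- cbind(shape$mv_center_x + shape$mv_radius * cos(theta),
                          shape$mv_radius * sin(theta), z_mv)
  # aortic annulus: horizontal cross-section of the tilted root (an ellipse)
  av_cx <- shape$ar_center_x + tan(shape$ar_tilt) * (z_av - dm$zb)
  aortic_annulus <- cbind(av_cx + ar_semi_x * cos(theta),
                          shape$ar_radius * sin(theta), z_av)

  mv_section <- internal_section_faces(
    mesh, z_mv, function(p) mv_channel(p) < 0.25 * h)
  # the aortic root is static, so the flux through the (flat, outward +z)
  # outlet cap equals the flux through the annulus plane
  av_section <- mesh$faces[lab == "AR_outlet", , drop = FALSE]
  pv_section <- mesh$faces[lab == "PV_inlet", , drop = FALSE]
  if (nrow(mv_section) == 0L || nrow(av_section) == 0L ||
      nrow(pv_section) == 0L) {
    stop("empty orifice flux section; mesh too coarse for the orifice radii")
  }

  vols <- mesh_cell_volumes(mesh)
  lv_analytic <- ellipsoid_cap_volume(dm$a, dm$c, shape$lv_trunc_frac) +
    pi * shape$mv_radius^2 * (z_mv - dm$zb) +
    pi * shape$ar_radius^2 * (z_av - dm$zb)

  static_dist <- function(pts) {
    pmin(mv_channel(pts), ar_cyl(pts), pv1(pts), pv2(pts))
  }

  geom <- structure(list(
    mesh = mesh, params = params, shape = shape, dims = dm,
    cell_region = region, apex_cells = apex_cells, laa_cells = laa_cells,
    face_label = face_label,
    wall_nodes = wall_nodes, open_nodes = open_nodes,
    inlet_nodes = inlet_nodes, outlet_nodes = outlet_nodes,
    mitral_annulus = mitral_annulus, aortic_annulus = aortic_annulus,
    z_mv = z_mv, z_av = z_av,
    mv_section = mv_section, av_section = av_section,
    pv_section = pv_section,
    lv_analytic_volume = lv_analytic,
    reference_volume_LV = sum(vols[region == 1L]),
    reference_volume_LA = sum(vols[region == 2L]),
    lv_long_axis_length = sqrt(sum((c(shape$mv_center_x, 0, z_mv) -
                                      c(0, 0, -dm$c))^2)),
    static_dist = static_dist,
    probes = list(
      LV = list(center = c(shape$ar_center_x * 0.5, 0, dm$zb - 0.010),
                radius = 0.006),
      AR = list(center = c(shape$ar_center_x +
                             tan(shape$ar_tilt) * (z_av + 0.008 - dm$zb),
                           0, z_av + 0.008),
                radius = min(0.004, 0.7 * shape$ar_radius)),
      LA = list(center = c(shape$mv_center_x, 0, z_mv + 0.012),
                radius = 0.007)
    ),
    dilation = NULL
  ), class = "lh_geometry")

  if (!is.null(pts_final)) {
    geom$mesh$points <- pts_final
    vols <- mesh_cell_volumes(geom$mesh)
    geom$reference_volume_LV <- sum(vols[region == 1L])
    geom$reference_volume_LA <- sum(vols[region == 2L])
    geom$dilation <- dilation
    apex_z <- -dm$c - dilation["lv"] * (dm$c + dm$zb)
    geom$lv_long_axis_length <-
      sqrt(sum((c(shape$mv_center_x, 0, z_mv) - c(0, 0, apex_z))^2))
    if (abs(geom$reference_volume_LV - esv_target) / esv_target > 0.01) {
      stop("chamber dilation missed the target end-systolic volume")
    }
  }
  geom
}

# oriented faces at an interior grid plane z = z0, normal +z
#' @keywords internal
internal_section_faces <- function(mesh, z0, inside_fn) {
  tets <- mesh$tets
  f <- rbind(
    tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
    tets[, c(1, 4, 3)], tets[, c(2, 3, 4)]
  )
  zc <- matrix(mesh$points[f, 3], nrow(f), 3)
  tol <- 1e-6 * mesh$h
  onp <- abs(zc[, 1] - z0) < tol & abs(zc[, 2] - z0) < tol &
    abs(zc[, 3] - z0) < tol
  f <- f[onp, , drop = FALSE]
  if (nrow(f) == 0L) return(f)
  s1 <- pmin(f[, 1], f[, 2], f[, 3]); s3 <- pmax(f[, 1], f[, 2], f[, 3])
  s2 <- as.numeric(f[, 1]) + f[, 2] + f[, 3] - s1 - s3
  nv <- max(f) + 1
  key <- (s1 * nv + s2) * nv + s3
  f <- f[!duplicated(key), , drop = FALSE]
  fg <- face_geometry(mesh$points, f)
  f <- f[inside_fn(fg$centroid), , drop = FALSE]
  if (nrow(f) == 0L) return(f)
  # orient all faces with normal +z
  fg <- face_geometry(mesh$points, f)
  flip <- fg$normal[, 3] < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  f
}

# outward-oriented closed surface of a cell region (logical over tets)
#' @keywords internal
region_closed_surface <- function(mesh, cells) {
  tets <- mesh$tets[cells, , drop = FALSE]
  f <- rbind(
    tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
    tets[, c(1, 4, 3)], tets[, c(2, 3, 4)]
  )
  s1 <- pmin(f[, 1], f[, 2], f[, 3]); s3 <- pmax(f[, 1], f[, 2], f[, 3])
  s2 <- as.numeric(f[, 1]) + f[, 2] + f[, 3] - s1 - s3
  nv <- max(f) + 1
  key <- (s1 * nv + s2) * nv + s3
  f[!(duplicated(key) | duplicated(key, fromLast = TRUE)), , drop = FALSE]
}

# Smooth motion/dilation displacement basis, faded to zero near the static
# structures (orifice channels, aortic root, vein stubs).
#  - LV: scaling about the LV base center (radial thickening + long-axis
#    shortening), amplitude dimensionless;
#  - LA: normalized-radius times surface-normal field (a uniform normal
#    offset at the wall, vanishing at the chamber center), amplitude in m.
#    The normal-offset form keeps the far ends of the elongated atrium from
#    amplifying the displacement, which would tangle the mesh.
#' @keywords internal
motion_basis <- function(geom, pts) {
  dm <- geom$dims
  s <- clamp01(geom$static_dist(pts) / geom$shape$taper_len)
  taper <- s * s * (3 - 2 * s)
  lam <- clamp01((pts[, 3] - dm$zb) / 0.016)
  lam <- lam * lam * (3 - 2 * lam) # 0 in LV, 1 in LA
  g_lv <- sweep(pts, 2, c(0, 0, dm$zb), "-") * (taper * (1 - lam))
  # LA: affine scaling about the atrial center (uniform strain, so the
  # elongated chamber empties and dilates without local crushing); the
  # z-motion of the atrial floor is faded near the ventricular base plane
  # so the expanding atrium does not crash into the base
  d_la <- sweep(pts, 2, dm$la_center, "-")
  ramp <- 0.45 * (dm$la_center[3] + dm$c_la - dm$zb)
  w_base <- clamp01((pts[, 3] - dm$zb) / ramp)
  w_base <- w_base * w_base * (3 - 2 * w_base)
  d_la[, 3] <- ifelse(d_la[, 3] < 0, d_la[, 3] * w_base, d_la[, 3])
  g_la <- d_la * (taper * lam)
  list(g_lv = g_lv, g_la = g_la)
}

#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# exact amplitude calibration: vertex positions are linear in the amplitude,
# so any region volume is a cubic polynomial in it
#' @keywords internal
calibrate_amplitude <- function(vol_fn, target, lower = -0.9, upper = 1.2) {
  ss <- seq(lower, upper, length.out = 4)
  vv <- vapply(ss, vol_fn, numeric(1))
  co <- solve(outer(ss, 0:3, "^"), vv) # exact cubic through 4 samples
  r <- polyroot(c(co[1] - target, co[2:4]))
  r <- Re(r)[abs(Im(r)) < 1e-7 * max(1, abs(Re(r)))]
  r <- r[r >= lower - 1e-9 & r <= upper + 1e-9]
  if (length(r) == 0L) {
    stop("requested chamber volume unreachable by the wall-motion ",
         "parameterization (amplitude outside [", lower, ", ", upper, "])")
  }
  r[which.min(abs(r))]
}

# calibrated chamber dilation of the template mesh (points only)
#' @keywords internal
.dilate_mesh <- function(mesh, region, pseudo, esv_target, la_target) {
  basis <- motion_basis(pseudo, mesh$points)
  lv_surf <- region_closed_surface(mesh, region == 1L)
  la_surf <- region_closed_surface(mesh, region == 2L)
  beta_lv <- calibrate_amplitude(function(b) {
    surface_enclosed_volume(mesh$points + b * basis$g_lv, lv_surf)
  }, esv_target, lower = -0.5, upper = 1.0)
  beta_la <- calibrate_amplitude(function(b) {
    surface_enclosed_volume(mesh$points + beta_lv * basis$g_lv +
                              b * basis$g_la, la_surf)
  }, la_target, lower = -0.4, upper = 0.6)
  pts <- mesh$points + beta_lv * basis$g_lv + beta_la * basis$g_la
  list(points = pts, betas = c(lv = beta_lv, la = beta_la))
}

#' @export
print.lh_geometry <- function(x, ...) {
  cat("<lh_geometry> scenario:", x$params$name, "\n")
  cat("  vertices:", nrow(x$mesh$points), " tets:", nrow(x$mesh$tets),
      " h:", x$mesh$h, "m\n")
  cat(sprintf("  LV volume: %.1f mL  LA volume: %.1f mL\n",
              m3_to_mL(x$reference_volume_LV),
              m3_to_mL(x$reference_volume_LA)))
  invisible(x)
}
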