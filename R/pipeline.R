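# End-to-end orchestration: scenario generation -> multi-cycle simulation ->
# ensemble statistics and indices -> summary table and artifacts; plus the
# small programmatic fixtures used by the test suite.

#' Post-process a run into ensemble statistics and indices
#'
#' Computes, from the stored phase-locked snapshots: ensemble mean/SD,
#' Reynolds stresses and tau_max with the hemolysis exposure report, GTKE
#' curves and time averages per chamber, the Pope criterion volume fraction,
#' wall shear stress of the ensemble velocity with TAWSS/OSI/RRT and the
#' area fractions above the stagnation threshold, ensemble flow-rate curves,
#' transvalvular pressure drops, the E-wave propagation index, and cardiac
#' event phases.
#'
#' @param run an `lh_run`.
#' @param geom the matching geometry.
#' @param rrt_threshold stagnation threshold on RRT, 1/Pa.
#' @param tau_threshold hemolysis threshold on tau_max, Pa.
#' @param rho density, kg/m^3.
#' @param mu viscosity, Pa s.
#' @return an `lh_analysis` list; `$summary` mirrors the per-subject index
#'   table (EPI, area percentages with RRT above threshold for LV, LV apex,
#'   LA and LAA, time-averaged GTKE in LV and LA in mJ, and the total
#'   tau_max exposure duration in ms).
#' @export
analyze_run <- function(run, geom, rrt_threshold = 5, tau_threshold = 800,
                        rho = 1060, mu = 3.5e-3) {
  stack <- cycle_stack(run, geom)
  stats <- ensemble_stats(stack)
  rey <- reynolds_stress(stack, rho)
  tau_nodal <- tau_max(rey)

  # cell-based tau for volume exposure
  tets <- geom$mesh$tets
  m <- stack$m
  tau_cell <- matrix(0, nrow(tets), m)
  for (ph in seq_len(m)) {
    tau_cell[, ph] <- rowMeans(matrix(tau_nodal[tets, ph], ncol = 4))
  }
  volmat <- do.call(cbind, stack$cell_volumes)
  expo <- exposure_metrics(tau_cell, tau_threshold, run$geom_params$period_T,
                           volmat)

  gtke_lv <- gtke(stats, stack, "LV", rho)
  gtke_la <- gtke(stats, stack, "LA", rho)
  pope <- pope_criterion(stats, stack, c_les = run$config$c_sigma,
                         delta = geom$mesh$h, rho = rho)

  # wall shear stress of the ensemble velocity on the wall faces
  wall_mask <- !(geom$face_label %in% c("PV_inlet", "AR_outlet"))
  wfaces <- geom$mesh$faces[wall_mask, , drop = FALSE]
  wowner <- wall_face_tets(geom$mesh)[wall_mask]
  wss <- array(0, c(nrow(wfaces), 3L, m))
  for (ph in seq_len(m)) {
    wss[, , ph] <- wall_shear_stress(stats$mean[, , ph],
                                     stack$phase_coords[[ph]],
                                     geom$mesh, wfaces, wowner, mu)
  }
  tawss_f <- tawss(wss)
  osi_f <- osi(wss)
  rrt_f <- rrt(tawss_f, osi_f)
  areas <- face_geometry(geom$mesh$points, wfaces)$area
  lab <- geom$face_label[wall_mask]
  area_frac <- c(
    LV = area_fraction_above(rrt_f, rrt_threshold, areas,
                             lab %in% c("LV", "LV_apex")),
    LV_apex = area_fraction_above(rrt_f, rrt_threshold, areas,
                                  lab == "LV_apex"),
    LA = area_fraction_above(rrt_f, rrt_threshold, areas,
                             lab %in% c("LA", "LAA")),
    LAA = area_fraction_above(rrt_f, rrt_threshold, areas, lab == "LAA")
  )

  # ensemble (phase-locked) flow-rate and pressure curves over the retained
  # cycles, at step resolution
  ser <- run$series
  keep <- ser$cycle > run$discard
  nsc <- sum(keep) / (run$n_cycles - run$discard)
  fold <- function(x) rowMeans(matrix(x[keep], nsc))
  ens <- data.frame(
    t = ser$t[seq_len(nsc)],
    q_mv = fold(ser$q_mv), q_av = fold(ser$q_av), q_pv = fold(ser$q_pv),
    p_lv = fold(ser$p_lv), p_la = fold(ser$p_la), p_ar = fold(ser$p_ar),
    v_lv = fold(ser$v_lv)
  )
  T <- run$geom_params$period_T

  # cardiac events from the ensemble curves
  sys_win <- ens$t < 0.55 * T
  # aortic valve closure: first decay of the ejection below 2% of its peak
  # after the systolic maximum (the end-diastolic reopening is ignored)
  i_pk <- which.max(ens$q_av)
  after <- which(ens$q_av < 0.02 * max(ens$q_av) &
                   seq_along(ens$q_av) > i_pk)
  t_av_close <- if (length(after)) ens$t[min(after)] else NA_real_
  dp_av_max <- max((ens$p_lv - ens$p_ar)[sys_win])
  dia_win <- ens$t > t_av_close & ens$t < 0.95 * T
  dp_mv_max <- max((ens$p_la - ens$p_lv)[dia_win])
  t_gtke_peak <- run$phase_times[which.max(gtke_lv + gtke_la)]

  epi_val <- tryCatch({
    epi(ens$q_mv, ens$t, pi * geom$shape$mv_radius^2,
        .lv_length_ed(geom, run), t_av_close)
  }, error = function(e) NA_real_)

  summary <- data.frame(
    scenario = run$geom_params$name,
    EPI = as.numeric(epi_val),
    area_rrt_LV = unname(area_frac["LV"]),
    area_rrt_LV_apex = unname(area_frac["LV_apex"]),
    area_rrt_LA = unname(area_frac["LA"]),
    area_rrt_LAA = unname(area_frac["LAA"]),
    gtke_lv_mj = 1e3 * mean(gtke_lv),
    gtke_la_mj = 1e3 * mean(gtke_la),
    exposure_ms = 1e3 * expo$total_exposure_time,
    pope_fraction_below = pope$mean_fraction_below,
    dp_av_max_mmHg = Pa_to_mmHg(dp_av_max),
    dp_mv_max_mmHg = Pa_to_mmHg(dp_mv_max)
  )

  structure(list(
    stats = stats, reynolds = rey, tau_nodal = tau_nodal,
    exposure = expo, gtke_lv = gtke_lv, gtke_la = gtke_la, pope = pope,
    wss = wss, tawss = tawss_f, osi = osi_f, rrt = rrt_f,
    wall_faces = wfaces, wall_labels = lab, wall_areas = areas,
    area_fractions = area_frac, ensemble_series = ens,
    events = list(t_av_close = t_av_close, t_gtke_peak = t_gtke_peak,
                  dp_av_max = dp_av_max, dp_mv_max = dp_mv_max),
    summary = summary
  ), class = "lh_analysis")
}

# Ventricular long-axis length (mitral annulus centroid to apex) at the
# end-diastolic configuration: the motion scales the ventricle about the
# base-plane center, so the apex moves by (V_ED / V_ES)^(1/3) - 1 times its
# offset from the base.
#' @keywords internal
.lv_length_ed <- function(geom, run) {
  esv <- geom$reference_volume_LV
  edv <- esv / (1 - geom$params$ejection_fraction)
  s_ed <- (edv / esv)^(1 / 3) - 1
  mvc <- c(geom$shape$mv_center_x, 0, geom$z_mv)
  z_apex_es <- geom$z_mv -
    sqrt(geom$lv_long_axis_length^2 - geom$shape$mv_center_x^2)
  z_apex_ed <- geom$dims$zb + (1 + s_ed) * (z_apex_es - geom$dims$zb)
  sqrt(sum((mvc - c(0, 0, z_apex_ed))^2))
}

#' Pipeline configuration
#'
#' @param scenario `"healthy"`, `"regurgitant"` or an [lh_scenario()].
#' @param output_dir where artifacts are written (`NULL` = no files).
#' @param n_cycles,discard_cycles heartbeat counts (override the scenario).
#' @param mesh_h mesh spacing override, m.
#' @param dt time step override, s.
#' @param n_phases snapshots per cycle.
#' @param seed perturbation seed.
#' @param write_fields write VTK field snapshots of the ensemble results.
#' @param ... further [lh_scenario()] overrides.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(scenario = "healthy", output_dir = NULL,
                            n_cycles = NULL, discard_cycles = NULL,
                            mesh_h = NULL, dt = NULL, n_phases = 50L,
                            seed = NULL, write_fields = FALSE, ...) {
  params <- if (inherits(scenario, "lh_scenario")) scenario else
    lh_scenario(scenario, ...)
  if (!is.null(n_cycles)) params$n_cycles <- n_cycles
  if (!is.null(discard_cycles)) params$discard_cycles <- discard_cycles
  if (!is.null(dt)) params$dt <- dt
  if (!is.null(seed)) params$perturbation_seed <- seed
  validate_scenario(params)
  structure(list(params = params, output_dir = output_dir,
                 mesh_h = mesh_h, n_phases = as.integer(n_phases),
                 write_fields = write_fields),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Generates the anatomy and motion, runs the heartbeats, computes the
#' ensemble statistics and indices, and (optionally) writes the artifacts:
#' geometry and ensemble fields as legacy VTK, scalar curves and the summary
#' table as CSV, the configuration as YAML, and a JSON manifest with file
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return list with `geom`, `motion`, `run`, `analysis`, and `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  params <- config$params
  if (params$discard_cycles >= params$n_cycles) {
    stop("discard_cycles must be smaller than n_cycles")
  }
  geom <- generate_anatomy(params, mesh_h = config$mesh_h)
  motion <- generate_motion(geom)
  scfg <- solver_config(dt = params$dt, delta = geom$mesh$h)
  sim <- lh_simulation(geom, motion, scfg)
  run <- run_cycles(sim, n_cycles = params$n_cycles,
                    discard = params$discard_cycles,
                    n_phases = config$n_phases,
                    seed = params$perturbation_seed, verbose = verbose)
  analysis <- analyze_run(run, geom)

  manifest <- list(scenario = params$name, n_cycles = params$n_cycles,
                   seed = params$perturbation_seed, files = list())
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    paths <- character(0)
    p <- file.path(od, "geometry.vtk")
    write_vtk(geom$mesh$points, geom$mesh$tets, p,
              cell_data = list(region = geom$cell_region))
    paths <- c(paths, p)
    p <- file.path(od, "summary.csv")
    write.csv(analysis$summary, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(od, "ensemble_series.csv")
    write.csv(analysis$ensemble_series, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(od, "gtke.csv")
    write.csv(data.frame(phase_s = run$phase_times,
                         gtke_lv_J = analysis$gtke_lv,
                         gtke_la_J = analysis$gtke_la), p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(od, "valve_events.csv")
    write.csv(run$events, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(od, "config.yaml")
    write_run_config(list(params = params, n_phases = config$n_phases), p)
    paths <- c(paths, p)
    if (config$write_fields) {
      ph_pk <- which.max(analysis$gtke_lv + analysis$gtke_la)
      p <- file.path(od, "ensemble_fields.vtk")
      write_vtk(run$phase_coords[[ph_pk]], geom$mesh$tets, p,
                point_data = list(
                  u_mean = analysis$stats$mean[, , ph_pk],
                  sd = analysis$stats$sd_mag[, ph_pk],
                  tau_max = analysis$tau_nodal[, ph_pk]
                ),
                cell_data = list(D = analysis$exposure$D))
      paths <- c(paths, p)
    }
    manifest$files <- lapply(paths, function(pp) {
      list(path = pp, md5 = unname(tools::md5sum(pp)))
    })
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(geom = geom, motion = motion, run = run, analysis = analysis,
       manifest = manifest)
}

#' Small programmatic test fixtures
#'
#' `"tiny-tube"`: a short cylindrical tube mesh with boundary node sets and
#' the analytic steady (Poiseuille) solution for a given pressure drop.
#' `"field-stack"`: a two-cycle phase-locked velocity stack on a small box
#' mesh with an exactly known per-component fluctuation variance, for
#' closed-form checks of the ensemble statistics.
#' `"tiny-heart"`: the healthy geometry and motion at the default desk
#' resolution.
#'
#' @param kind fixture id.
#' @param seed integer seed.
#' @param h mesh spacing for the tube fixture, m.
#' @return a list, by kind.
#' @export
make_fixtures <- function(kind = c("tiny-tube", "field-stack", "tiny-heart"),
                          seed = 1L, h = 8e-4) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "tiny-tube") {
    r <- 0.004; L <- 0.02
    cyl <- imp_cylinder_z(c(0, 0), r, 0, L)
    bb <- rbind(c(-r - 2.5 * h, -r - 2.5 * h, -2 * h),
                c(r + 2.5 * h, r + 2.5 * h, L + 2 * h))
    m <- voxel_tet_mesh(cyl, bb, h)
    fg <- face_geometry(m$points, m$faces)
    lab <- rep("wall", nrow(fg$centroid))
    lab[abs(fg$centroid[, 3]) < 0.3 * h] <- "inlet"
    lab[abs(fg$centroid[, 3] - L) < 0.3 * h] <- "outlet"
    wall_nodes <- unique(as.vector(m$faces[lab == "wall", , drop = FALSE]))
    open_nodes <- setdiff(unique(as.vector(m$faces[lab != "wall", ,
                                                   drop = FALSE])),
                          wall_nodes)
    inlet_nodes <- setdiff(unique(as.vector(m$faces[lab == "inlet", ,
                                                    drop = FALSE])),
                           wall_nodes)
    poiseuille <- function(dp, mu) {
      rr2 <- m$points[, 1]^2 + m$points[, 2]^2
      dp / (4 * mu * L) * pmax(r^2 - rr2, 0)
    }
    list(mesh = m, radius = r, length = L, labels = lab,
         wall_nodes = wall_nodes, open_nodes = open_nodes,
         inlet_nodes = inlet_nodes,
         open_faces = m$faces[lab != "wall", , drop = FALSE],
         poiseuille_uz = poiseuille)
  } else if (kind == "field-stack") {
    box <- imp_cylinder_z(c(0, 0), 0.02, 0, 0.01)
    m <- voxel_tet_mesh(box, rbind(c(-0.024, -0.024, -0.004),
                                   c(0.024, 0.024, 0.014)), 2e-3)
    n <- nrow(m$points)
    n_ph <- 4L
    U <- matrix(rnorm(3 * n, sd = 0.2), n, 3)
    s <- 0.1
    u <- array(0, c(n, 3L, n_ph, 2L))
    for (ph in 1:n_ph) {
      u[, , ph, 1] <- U + s
      u[, , ph, 2] <- U - s # population SD exactly s per component
    }
    vol <- tet_geom_cpp(m$points, m$tets)$vol
    list(mesh = m, u = u, s = s, base = U, n_phases = n_ph,
         cell_volumes = vol, volume = sum(vol))
  } else {
    params <- lh_scenario("healthy")
    geom <- generate_anatomy(params)
    list(geom = geom, motion = generate_motion(geom))
  }
}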