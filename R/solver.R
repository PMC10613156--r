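# Heart-cycle simulation driver: boundary pressure waveforms, the coupled
# mesh-motion / valve / flow loop, and multi-cycle orchestration with
# phase-locked snapshot storage.

#' Boundary pressure waveforms
#'
#' Periodic pressures imposed as normal stresses at the pulmonary-vein inlets
#' and the aortic-root outlet. The healthy venous pressure is constant
#' (10 mmHg); the regurgitant venous profile rises during systole to a
#' configurable peak (default 40 mmHg) as the regurgitant jet loads the
#' atrium. The aortic profile is a physiological diastolic-base/systolic-bump
#' waveform.
#'
#' @param t time, s (wrapped periodically).
#' @param params an [lh_scenario()] (fields `period_T`,
#'   `venous_pressure_profile`, `venous_pressure`, `venous_peak`,
#'   `aortic_pressure_profile`, `t_es_frac`).
#' @return list with `p_pv` and `p_ar`, Pa.
#' @examples
#' pressure_waveforms(0.2, lh_scenario("healthy"))$p_pv # 1333.22 Pa
#' @export
pressure_waveforms <- function(t, params) {
  T <- params$period_T
  phi <- (t / T) %% 1
  bump <- function(phi, a, b) {
    ifelse(phi > a & phi < b, sin(pi * (phi - a) / (b - a))^2, 0)
  }
  p_ar <- switch(params$aortic_pressure_profile,
    physiological = mmHg_to_Pa(80 + 40 * bump(phi, 0.02,
                                              params$t_es_frac + 0.08)),
    stop("unknown aortic pressure profile id: ",
         params$aortic_pressure_profile)
  )
  p_pv <- switch(params$venous_pressure_profile,
    constant = rep(params$venous_pressure, length(phi)),
    elevated = params$venous_pressure +
      (params$venous_peak - params$venous_pressure) *
        bump(phi, 0.05, params$t_es_frac + 0.12),
    stop("unknown venous pressure profile id: ",
         params$venous_pressure_profile)
  )
  list(p_pv = unname(p_pv), p_ar = unname(p_ar))
}

#' Assemble a left-heart simulation
#'
#' Wires together the geometry, wall motion, elastic mesh-motion extension,
#' flow problem and resistive valve surfaces into a ready-to-run simulation.
#'
#' @param geom an [generate_anatomy()] geometry.
#' @param motion an [generate_motion()] result (generated if missing).
#' @param config [solver_config()].
#' @param props [fluid_properties()].
#' @param eps_gamma,r_gamma resistive valve layer parameters. The default
#'   half-thickness is `max(0.75e-3, 1.2 h)`: the smoothed layer must span at
#'   least one mesh spacing, otherwise most vertices miss its support and the
#'   closed valve becomes porous (the kernel keeps unit mass either way).
#' @param extension_type `"elastic"` or `"harmonic"` mesh-motion extension.
#' @return an `lh_simulation` environment.
#' @export
lh_simulation <- function(geom, motion = NULL, config = solver_config(),
                          props = fluid_properties(),
                          eps_gamma = NULL, r_gamma = 1e5,
                          extension_type = "elastic") {
  stopifnot(inherits(geom, "lh_geometry"))
  if (is.null(eps_gamma)) eps_gamma <- max(0.75e-3, 1.2 * geom$mesh$h)
  if (is.null(motion)) motion <- generate_motion(geom)
  sim <- new.env(parent = emptyenv())
  sim$geom <- geom
  sim$params <- geom$params
  sim$motion <- motion
  sim$cm <- continuous_motion(motion)
  sim$ext <- extension_operator(geom$mesh, type = extension_type)
  open_faces <- rbind(geom$pv_section, geom$av_section)
  sim$problem <- flow_setup(geom$mesh, geom$wall_nodes, geom$open_nodes,
                            open_faces, props, config)
  sim$valves <- list(
    mv_open = valve_surface(geom, "mitral", "open", eps_gamma, r_gamma),
    mv_closed = valve_surface(geom, "mitral", "closed", eps_gamma, r_gamma),
    av_open = valve_surface(geom, "aortic", "open", eps_gamma, r_gamma),
    av_closed = valve_surface(geom, "aortic", "closed", eps_gamma, r_gamma)
  )
  # The valve layers sit in the geometrically static orifice region, so the
  # nodal kernel of each configuration is precomputed on the reference mesh.
  # At desk resolution the smoothed layer spans at least one mesh spacing,
  # which would plug the small open-configuration funnels; the open valves
  # therefore exert no resistance (their surfaces remain available for
  # geometry output and the module-level kernel operations).
  pts <- geom$mesh$points
  coef <- r_gamma / eps_gamma
  zero <- numeric(nrow(pts))
  sim$riis <- list(
    mv_open = zero, av_open = zero,
    mv_closed = coef * riis_delta(pts, sim$valves$mv_closed,
                                  eps_gamma = eps_gamma),
    av_closed = coef * riis_delta(pts, sim$valves$av_closed,
                                  eps_gamma = eps_gamma)
  )
  sim$probe_nodes <- lapply(geom$probes, function(pb) {
    which(sqrt(rowSums(sweep(pts, 2, pb$center)^2)) < pb$radius)
  })
  for (nm in names(sim$probe_nodes)) {
    if (length(sim$probe_nodes[[nm]]) == 0L) {
      stop("pressure probe ", nm, " contains no mesh vertices")
    }
  }
  sim$is_inlet <- geom$open_nodes %in% geom$inlet_nodes
  class(sim) <- c("lh_simulation", "environment")
  sim
}

# divergence-free perturbation: sum of localized vector-potential bumps in
# the atrium (the curl is taken analytically, so the field is solenoidal)
#' @keywords internal
inflow_perturbation <- function(geom, amplitude, seed_offset) {
  set.seed(seed_offset %% .Machine$integer.max)
  pts <- geom$mesh$points
  dm <- geom$dims
  u <- matrix(0, nrow(pts), 3)
  for (b in 1:3) {
    ctr <- dm$la_center + c(runif(1, -0.3, 0.3) * dm$a_la,
                            runif(1, -0.5, 0.5) * dm$b_la,
                            runif(1, -0.3, 0.3) * dm$c_la)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    sig <- 0.008
    d <- sweep(pts, 2, ctr)
    g <- exp(-rowSums(d^2) / (2 * sig^2))
    # curl of (psi * ax) with psi Gaussian: grad(psi) x ax
    gp <- -d * g / sig^2
    cu <- cbind(gp[, 2] * ax[3] - gp[, 3] * ax[2],
                gp[, 3] * ax[1] - gp[, 1] * ax[3],
                gp[, 1] * ax[2] - gp[, 2] * ax[1])
    u <- u + cu * (amplitude * sig / 3)
  }
  u
}

#' Run heart cycles
#'
#' Advances the simulation over `n_cycles` heartbeats from the null initial
#' condition, switching the valves by the on-off rules each step, injecting
#' a small seeded divergence-free velocity perturbation into the atrium at
#' each cycle start (a stand-in for natural cycle-to-cycle decorrelation),
#' and storing phase-locked snapshots for the retained cycles.
#'
#' @param sim an [lh_simulation()].
#' @param n_cycles number of simulated heartbeats.
#' @param discard initial heartbeats excluded from the snapshot stack.
#' @param n_phases phase-locked snapshots per cycle (coerced to a divisor of
#'   the steps per cycle).
#' @param seed integer seed for the cycle perturbations.
#' @param verbose print per-cycle progress.
#' @return an `lh_run`: per-step `series` (times, flow rates, probe
#'   pressures, valve states, diagnostics), the snapshot stack (`u_snap`
#'   `[node, component, phase, cycle]`, `musgs_snap` `[cell, phase, cycle]`,
#'   `phase_coords`), the valve event log, and run metadata.
#' @export
run_cycles <- function(sim, n_cycles = sim$params$n_cycles,
                       discard = sim$params$discard_cycles,
                       n_phases = 50L,
                       seed = sim$params$perturbation_seed,
                       verbose = FALSE) {
  stopifnot(inherits(sim, "lh_simulation"), n_cycles >= discard + 1)
  geom <- sim$geom
  params <- sim$params
  pr <- sim$problem
  cfg <- pr$config
  T <- params$period_T
  dt <- cfg$dt
  nsc <- round(T / dt)
  if (abs(nsc * dt - T) > 1e-9) {
    stop("period_T must be an integer multiple of the time step dt")
  }
  while (nsc %% n_phases != 0L) n_phases <- n_phases - 1L
  stride <- nsc %/% n_phases
  n_ret <- n_cycles - discard
  n <- pr$n

  # perturbation amplitude from the peak mitral filling speed of the
  # prescribed volume curve
  qmax <- max(abs(diff(sim$motion$v_lv_target)) /
                (T / params$n_frames))
  a_mv <- pi * geom$shape$mv_radius^2
  pert_amp <- params$perturbation_frac * qmax / a_mv

  ref <- geom$mesh$points
  state <- flow_state_init(pr)
  vstate <- valve_state_init(guard_frac = 0.77 / 0.8)
  # The boundary displacement is spanned by the two motion basis fields with
  # spline-interpolated amplitudes, and the elastic extension is linear: the
  # interior displacement at any time is the same amplitude combination of
  # the two extended basis fields (no per-step extension solve needed).
  bnodes <- sim$motion$bnodes
  bb <- motion_basis(geom, ref[bnodes, , drop = FALSE])
  D_lv <- extend_displacement(sim$ext, bb$g_lv)
  D_la <- extend_displacement(sim$ext, bb$g_la)
  amp_spline <- periodic_spline(cbind(sim$motion$amp_lv, sim$motion$amp_la),
                                T)
  mesh_at <- function(tt) {
    a <- eval_periodic_spline(amp_spline, tt)
    ref + a[1] * D_lv + a[2] * D_la
  }
  coords_prev <- mesh_at(0)

  total_steps <- n_cycles * nsc
  ser <- list(t = numeric(total_steps), q_mv = numeric(total_steps),
              q_av = numeric(total_steps), q_pv = numeric(total_steps),
              p_lv = numeric(total_steps), p_la = numeric(total_steps),
              p_ar = numeric(total_steps), ke = numeric(total_steps),
              div_rms = numeric(total_steps), cfl = numeric(total_steps),
              mv_open = logical(total_steps), av_open = logical(total_steps),
              v_lv = numeric(total_steps), cycle = integer(total_steps))
  u_snap <- array(0, c(n, 3L, n_phases, n_ret))
  musgs_snap <- array(0, c(nrow(pr$tets), n_phases, n_ret))
  phase_coords <- vector("list", n_phases)
  lv_surf <- region_closed_surface(geom$mesh, geom$cell_region == 1L)
  v_prev <- surface_enclosed_volume(coords_prev, lv_surf)
  v_prev2 <- v_prev

  istep <- 0L
  for (cyc in seq_len(n_cycles)) {
    state$u <- state$u +
      inflow_perturbation(geom, pert_amp, seed + 1000L * cyc)
    for (k in seq_len(nsc)) {
      istep <- istep + 1L
      tt <- (k * dt) %% T
      coords <- mesh_at(tt)
      if (k %% 25L == 1L) { # motion safety is guaranteed by construction
        vols <- tet_geom_cpp(coords, pr$tets)$vol
        if (any(vols <= 0)) {
          rp <- repair_tet_mesh(coords, pr$tets, pr$adj)
          if (!rp$ok) stop("mesh tangled at t = ", tt, " s; aborting run")
          coords <- rp$points
        }
      }
      u_ale <- (coords - coords_prev) / dt

      # Valve switching from end-of-previous-step fields. The aortic and
      # venous flow rates are boundary-cap integrals (complete coverage);
      # the mitral flow rate comes from ventricular mass conservation,
      # Q_MV = dV_LV/dt + Q_AV, because the on-grid interior section cannot
      # cover the beveled orifice rim at desk resolution.
      q_av <- valve_flow_rate(state$u, coords_prev, geom$av_section)
      q_mv <- (v_prev - v_prev2) / dt + q_av
      q_pv <- -valve_flow_rate(state$u, coords_prev, geom$pv_section)
      p_probe <- vapply(sim$probe_nodes, function(ix) mean(state$p[ix]),
                        numeric(1))
      vstate <- update_valve_state(vstate,
                                   dp_av = p_probe[["LV"]] - p_probe[["AR"]],
                                   dp_mv = p_probe[["LA"]] - p_probe[["LV"]],
                                   q_av = q_av, q_mv = q_mv,
                                   t = (cyc - 1) * T + k * dt, T = T)
      riis_diag <- (if (vstate$mv == "open") sim$riis$mv_open else
        sim$riis$mv_closed) +
        (if (vstate$av == "open") sim$riis$av_open else sim$riis$av_closed)

      pw <- pressure_waveforms(k * dt, params)
      p_bc <- ifelse(sim$is_inlet, pw$p_pv, pw$p_ar)
      wall_values <- u_ale[geom$wall_nodes, , drop = FALSE]
      state <- advance_time_step(pr, state, coords, u_ale, wall_values,
                                 p_bc, riis_diag,
                                 t_new = (cyc - 1) * T + k * dt)

      ser$t[istep] <- (cyc - 1) * T + k * dt
      ser$q_mv[istep] <- q_mv; ser$q_av[istep] <- q_av
      ser$q_pv[istep] <- q_pv
      ser$p_lv[istep] <- p_probe[["LV"]]; ser$p_la[istep] <- p_probe[["LA"]]
      ser$p_ar[istep] <- p_probe[["AR"]]
      ser$ke[istep] <- if (k %% stride == 0L) {
        flow_kinetic_energy(pr, state, coords)
      } else if (istep > 1L) ser$ke[istep - 1L] else 0
      ser$div_rms[istep] <- state$div_rms; ser$cfl[istep] <- state$cfl
      ser$mv_open[istep] <- vstate$mv == "open"
      ser$av_open[istep] <- vstate$av == "open"
      v_new <- surface_enclosed_volume(coords, lv_surf)
      ser$v_lv[istep] <- v_new
      v_prev2 <- v_prev
      v_prev <- v_new
      ser$cycle[istep] <- cyc

      if (k %% stride == 0L && cyc > discard) {
        ph <- k %/% stride
        u_snap[, , ph, cyc - discard] <- state$u
        musgs_snap[, ph, cyc - discard] <- state$mu_sgs
        if (cyc == discard + 1L) phase_coords[[ph]] <- coords
      }
      coords_prev <- coords
    }
    if (verbose) {
      message(sprintf("cycle %d/%d done (KE %.3g J, max CFL %.2f)",
                      cyc, n_cycles, ser$ke[istep],
                      max(ser$cfl[ser$cycle == cyc])))
    }
  }

  structure(list(
    series = as.data.frame(ser),
    u_snap = u_snap, musgs_snap = musgs_snap,
    phase_coords = phase_coords,
    phase_times = (seq_len(n_phases)) * stride * dt,
    n_phases = n_phases, n_cycles = n_cycles, discard = discard,
    events = vstate$events, geom_params = params,
    config = cfg, seed = seed
  ), class = "lh_run")
}

#' @export
print.lh_run <- function(x, ...) {
  cat("<lh_run>", x$geom_params$name, ":", x$n_cycles, "cycles (",
      x$n_cycles - x$discard, "retained ),", x$n_phases, "phases/cycle\n")
  cat(sprintf("  peak |Q_MV| %.0f mL/s  peak |Q_AV| %.0f mL/s  max CFL %.2f\n",
              1e6 * max(abs(x$series$q_mv)), 1e6 * max(abs(x$series$q_av)),
              max(x$series$cfl)))
  invisible(x)
}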