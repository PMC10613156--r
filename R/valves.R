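# Resistive immersed valve surfaces and the on-off switching rules.
#
# Each valve is a triangulated leaflet surface in an open and a closed
# configuration. The flow solver adds a penalty (R_Gamma / eps_Gamma)
# (u - u_ALE) delta_Gamma on a smoothed layer of half-thickness eps_Gamma
# around the active configuration, forcing the fluid to the surface
# velocity. Valves open instantaneously when their transvalvular pressure
# difference becomes positive and close when their flow rate reverses (the
# mitral closure additionally guarded to a late-cycle window).

#' Build a valve leaflet surface
#'
#' Constructs the triangulated mitral or aortic leaflet surface in the open
#' or closed configuration for a given geometry. The closed mitral leaflet
#' is a flat disc sealing the mitral channel at the annulus plane; with a
#' positive `regurgitant_orifice_area` it becomes an annular disc with a
#' central hole of that area. The open mitral configuration is a short
#' funnel (tapered tube) hanging from the annulus into the ventricle. The
#' closed aortic leaflet is the elliptical cross-section of the tilted root
#' at the annulus; the open configuration is a tube along the root wall.
#'
#' @param geom an [generate_anatomy()] geometry.
#' @param kind `"mitral"` or `"aortic"`.
#' @param configuration `"open"` or `"closed"`.
#' @param eps_gamma half-thickness of the resistive layer, m.
#' @param r_gamma resistance coefficient, kg/(m s).
#' @param n_theta azimuthal resolution.
#' @return a `valve_surface`: `points`, `tris`, the annulus attachment ring
#'   indices, and the resistive parameters.
#' @export
valve_surface <- function(geom, kind = c("mitral", "aortic"),
                          configuration = c("open", "closed"),
                          eps_gamma = 0.75e-3, r_gamma = 1e5,
                          n_theta = 28L) {
  kind <- match.arg(kind)
  configuration <- match.arg(configuration)
  stopifnot(eps_gamma > 0, r_gamma > 0)
  sh <- geom$shape
  if (kind == "mitral") {
    center <- c(sh$mv_center_x, 0, geom$z_mv)
    if (configuration == "closed") {
      roa <- geom$params$regurgitant_orifice_area
      r_hole <- if (roa > 0) sqrt(roa / pi) else 0
      s <- .disc_surface(center, sh$mv_radius, r_hole, n_theta)
    } else {
      s <- .frustum_surface(center, axis = c(0, 0, -1), r0 = sh$mv_radius,
                            r1 = 0.75 * sh$mv_radius, len = 0.012, n_theta)
    }
  } else {
    z_av <- geom$z_av
    tilt <- sh$ar_tilt
    cx <- sh$ar_center_x + tan(tilt) * (z_av - geom$dims$zb)
    center <- c(cx, 0, z_av)
    if (configuration == "closed") {
      # flat elliptical disc: the horizontal cross-section of the root
      s <- .disc_surface(center, sh$ar_radius, 0, n_theta,
                         x_stretch = 1 / cos(tilt))
    } else {
      s <- .frustum_surface(center, axis = c(sin(tilt), 0, cos(tilt)),
                            r0 = sh$ar_radius * 0.98,
                            r1 = sh$ar_radius * 0.85, len = 0.008, n_theta)
    }
  }
  structure(c(s, list(kind = kind, configuration = configuration,
                      eps_gamma = eps_gamma, r_gamma = r_gamma)),
            class = "valve_surface")
}

# flat (possibly annular, possibly x-stretched) disc in the z plane
.disc_surface <- function(center, r_out, r_in, n_theta, x_stretch = 1) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  n_r <- max(3L, ceiling((r_out - r_in) / (r_out / 4)))
  rs <- seq(r_in, r_out, length.out = n_r + 1)
  pts <- NULL; ring_start <- integer(0)
  if (r_in <= 0) {
    pts <- matrix(center, 1, 3)
    rs <- rs[-1]
  }
  for (r in rs) {
    ring_start <- c(ring_start, nrow(pts %||% matrix(0, 0, 3)) + 1L)
    ring <- cbind(center[1] + r * cos(th) * x_stretch,
                  center[2] + r * sin(th), center[3])
    pts <- rbind(pts, ring)
  }
  tris <- NULL
  if (r_in <= 0) {
    # center fan to the first ring
    first <- ring_start[1]
    for (k in seq_len(n_theta)) {
      k2 <- (k %% n_theta) + 1L
      tris <- rbind(tris, c(1L, first + k - 1L, first + k2 - 1L))
    }
  }
  nr_rings <- length(ring_start)
  if (nr_rings > 1) {
    for (j in seq_len(nr_rings - 1)) {
      a <- ring_start[j]; b <- ring_start[j + 1]
      for (k in seq_len(n_theta)) {
        k2 <- (k %% n_theta) + 1L
        tris <- rbind(tris,
                      c(a + k - 1L, b + k - 1L, b + k2 - 1L),
                      c(a + k - 1L, b + k2 - 1L, a + k2 - 1L))
      }
    }
  }
  annulus <- ring_start[nr_rings] + seq_len(n_theta) - 1L
  list(points = pts, tris = tris, annulus_idx = annulus)
}

# open frustum (tube) from the annulus ring along an axis
.frustum_surface <- function(center, axis, r0, r1, len, n_theta,
                             n_axial = 4L) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ss <- seq(0, len, length.out = n_axial + 1)
  pts <- NULL
  for (i in seq_along(ss)) {
    r <- r0 + (r1 - r0) * ss[i] / len
    ring <- matrix(rep(center + ss[i] * axis, each = n_theta), n_theta, 3) +
      r * (cos(th) %o% e1 + sin(th) %o% e2)
    pts <- rbind(pts, ring)
  }
  tris <- NULL
  for (i in seq_len(n_axial)) {
    a <- (i - 1L) * n_theta; b <- i * n_theta
    for (k in seq_len(n_theta)) {
      k2 <- (k %% n_theta) + 1L
      tris <- rbind(tris,
                    c(a + k, b + k, b + k2),
                    c(a + k, b + k2, a + k2))
    }
  }
  list(points = pts, tris = tris, annulus_idx = seq_len(n_theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smoothed resistive-layer kernel of a valve
#'
#' Evaluates the smoothed Dirac layer `delta_Gamma` at arbitrary points: a
#' cosine bump `(1 + cos(pi d / eps)) / (2 eps)` of the unsigned distance
#' `d` to the leaflet surface, compactly supported within `eps_gamma` of the
#' surface and with unit integral across the layer thickness.
#'
#' @param points `m x 3` query points, m.
#' @param valve a `valve_surface`.
#' @param eps_gamma optional override of the layer half-thickness, m.
#' @return kernel values, 1/m.
#' @export
riis_delta <- function(points, valve, eps_gamma = valve$eps_gamma) {
  stopifnot(inherits(valve, "valve_surface"), eps_gamma > 0)
  tri9 <- cbind(valve$points[valve$tris[, 1], , drop = FALSE],
                valve$points[valve$tris[, 2], , drop = FALSE],
                valve$points[valve$tris[, 3], , drop = FALSE])
  d <- tri_min_dist_cpp(as.matrix(points), tri9)
  ifelse(d <= eps_gamma, (1 + cos(pi * d / eps_gamma)) / (2 * eps_gamma), 0)
}

#' Initialize the valve state machine
#'
#' @param mv,av initial status, `"open"` or `"closed"`.
#' @param guard_frac cycle fraction after which the mitral valve may close
#'   on flow reversal (the late-diastolic guard); the window wraps into the
#'   first `early_frac` of the next cycle so a reversal just after the cycle
#'   boundary still closes the valve.
#' @param early_frac see above.
#' @param dwell minimum time between successive switches of the same valve,
#'   s; suppresses the open/close chatter a discrete on-off rule produces
#'   around a flow-rate zero crossing.
#' @return a `valve_state` list with an empty event log.
#' @export
valve_state_init <- function(mv = "closed", av = "closed",
                             guard_frac = 0.77 / 0.8, early_frac = 0.10,
                             dwell = 0.005) {
  structure(list(mv = mv, av = av, guard_frac = guard_frac,
                 early_frac = early_frac, dwell = dwell,
                 last_switch = c(mv = -Inf, av = -Inf),
                 events = data.frame(time = numeric(0), valve = character(0),
                                     transition = character(0))),
            class = "valve_state")
}

#' Update the valve states by the on-off rules
#'
#' A closed valve opens when its transvalvular pressure difference
#' (upstream minus downstream) becomes positive. The open aortic valve
#' closes when its flow rate reverses. The open mitral valve closes when its
#' flow rate reverses *and* the cycle phase lies in the late-diastolic guard
#' window (or its wrap into early systole): mid-diastolic flow reversals
#' must not close the valve. Closure rules are evaluated before opening
#' rules; at most one switch per valve per step.
#'
#' @param state a `valve_state`.
#' @param dp_av,dp_mv pressure differences LV-AR and LA-LV, Pa.
#' @param q_av,q_mv flow rates through the valves (positive = physiological
#'   forward flow), m^3/s.
#' @param t time, s.
#' @param T cycle period, s.
#' @return the updated `valve_state`.
#' @export
update_valve_state <- function(state, dp_av, dp_mv, q_av, q_mv, t, T) {
  stopifnot(inherits(state, "valve_state"), T > 0)
  phase <- (t / T) %% 1
  log_event <- function(st, valve, transition) {
    st$events <- rbind(st$events,
                       data.frame(time = t, valve = valve,
                                  transition = transition))
    st
  }
  dwell <- state$dwell %||% 0
  ls <- state$last_switch %||% c(mv = -Inf, av = -Inf)
  # closure first
  if (t - ls[["av"]] >= dwell) {
    if (state$av == "open" && q_av < 0) {
      state$av <- "closed"; state <- log_event(state, "AV", "close")
      ls[["av"]] <- t
    } else if (state$av == "closed" && dp_av > 0) {
      state$av <- "open"; state <- log_event(state, "AV", "open")
      ls[["av"]] <- t
    }
  }
  mv_guard <- phase > state$guard_frac || phase < state$early_frac
  if (t - ls[["mv"]] >= dwell) {
    if (state$mv == "open" && q_mv < 0 && mv_guard) {
      state$mv <- "closed"; state <- log_event(state, "MV", "close")
      ls[["mv"]] <- t
    } else if (state$mv == "closed" && dp_mv > 0) {
      state$mv <- "open"; state <- log_event(state, "MV", "open")
      ls[["mv"]] <- t
    }
  }
  state$last_switch <- ls
  state
}

#' Flow rate through an oriented triangulated section
#'
#' Integrates `u . n` over the section, exactly for a piecewise-linear
#' velocity (each triangle contributes its area times the mean of the nodal
#' normal velocities).
#'
#' @param u nodal velocity (`n x 3`), m/s.
#' @param coords vertex coordinates of the mesh the section lives on.
#' @param faces `F x 3` oriented triangles (positive = forward flow).
#' @param orientation +1 or -1 to flip the stored orientation.
#' @return flow rate, m^3/s.
#' @export
valve_flow_rate <- function(u, coords, faces, orientation = 1) {
  if (is.null(faces) || nrow(faces) == 0L) stop("empty/unoriented section")
  fg <- face_geometry(coords, faces)
  un <- (rowSums(matrix(u[faces, 1], ncol = 3) / 3) * fg$normal[, 1] +
           rowSums(matrix(u[faces, 2], ncol = 3) / 3) * fg$normal[, 2] +
           rowSums(matrix(u[faces, 3], ncol = 3) / 3) * fg$normal[, 3])
  orientation * sum(fg$area * un)
}

#' Move a valve with the domain
#'
#' Displaces the leaflet surface by an arbitrary displacement field
#' evaluated at its vertices (the ALE movement of the surrounding domain),
#' so the annulus stays attached to the moving wall.
#'
#' @param valve a `valve_surface`.
#' @param disp_fun function mapping an `m x 3` point matrix to an `m x 3`
#'   displacement matrix, m.
#' @return the displaced `valve_surface`.
#' @export
move_valve_with_domain <- function(valve, disp_fun) {
  stopifnot(inherits(valve, "valve_surface"))
  valve$points <- valve$points + disp_fun(valve$points)
  valve
}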