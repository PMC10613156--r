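# Prescribed wall motion: physiological chamber volume curves sampled at the
# cine frame rate, turned into per-frame wall displacement fields by exact
# cubic amplitude calibration against the discrete chamber volumes.

#' Chamber volume curves over one heartbeat
#'
#' `lv_volume_curve` produces the left-ventricular cavity volume at cycle
#' phase `phi` in `[0, 1]` (`phi = t/T`, cycle starting at systole onset):
#' a smooth systolic ejection from EDV to ESV ending at `t_es_frac`, an
#' E-wave refilling `e_frac` of the stroke volume, a diastasis with a small
#' dip (producing the mid-diastolic mitral flow reversal), an A-wave
#' completing the filling, and a slight end-cycle decline that triggers the
#' final mitral flow reversal before valve closure. `la_volume_curve` is the
#' counter-phased atrial reservoir/conduit/booster curve, maximal at end
#' systole.
#'
#' @param phi cycle phase in `[0, 1]` (recycled/wrapped).
#' @param edv,esv LV end-diastolic and end-systolic volumes, m^3.
#' @param t_es_frac end-systolic phase.
#' @param e_frac fraction of the stroke volume refilled during the E-wave.
#' @param e_len E-wave duration as a cycle fraction.
#' @param dia_dip diastasis dip as a fraction of stroke volume.
#' @param t_dia_end,t_a_end diastasis and A-wave end phases.
#' @param end_dip end-cycle decline as a fraction of stroke volume.
#' @return volume, m^3 (vectorized over `phi`).
#' @export
lv_volume_curve <- function(phi, edv, esv, t_es_frac,
                            e_frac = 0.72, e_len = 0.22, dia_dip = 0.02,
                            t_dia_end = 0.80, t_a_end = 0.97,
                            end_dip = 0.005) {
  stopifnot(edv > esv, esv > 0, t_es_frac > 0,
            t_es_frac + e_len < t_dia_end, t_dia_end < t_a_end, t_a_end < 1)
  phi <- phi - floor(phi)
  sv <- edv - esv
  edvp <- edv - end_dip * sv
  p1 <- t_es_frac; p2 <- t_es_frac + e_len
  v2 <- esv + e_frac * sv
  dd <- dia_dip * sv
  dip_len <- min(0.18, t_dia_end - p2)
  dip_lo <- t_dia_end - dip_len
  v <- numeric(length(phi))
  s <- phi < p1
  v[s] <- edvp - (edvp - esv) * (1 - cos(pi * phi[s] / p1)) / 2
  s <- phi >= p1 & phi < p2
  v[s] <- esv + (v2 - esv) * (1 - cos(pi * (phi[s] - p1) / (p2 - p1))) / 2
  s <- phi >= p2 & phi < dip_lo
  v[s] <- v2
  s <- phi >= dip_lo & phi < t_dia_end
  v[s] <- v2 - dd * (1 - cos(2 * pi * (phi[s] - dip_lo) / dip_len)) / 2
  s <- phi >= t_dia_end & phi < t_a_end
  v[s] <- v2 + (edv - v2) *
    (1 - cos(pi * (phi[s] - t_dia_end) / (t_a_end - t_dia_end))) / 2
  s <- phi >= t_a_end
  v[s] <- edv - end_dip * sv * (1 - cos(pi * (phi[s] - t_a_end) / (1 - t_a_end))) / 2
  v
}

#' @rdname lv_volume_curve
#' @param v_ref atrial reservoir (end-systolic) volume, m^3.
#' @param la_ef atrial total emptying fraction.
#' @param e_frac_la fraction of atrial emptying during the E-wave.
#' @export
la_volume_curve <- function(phi, v_ref, la_ef, t_es_frac,
                            e_frac_la = 0.65, e_len = 0.22,
                            t_dia_end = 0.80, t_a_end = 0.97) {
  stopifnot(v_ref > 0, la_ef > 0, la_ef < 1)
  phi <- phi - floor(phi)
  vmin <- (1 - la_ef) * v_ref
  amp <- v_ref - vmin
  p1 <- t_es_frac; p2 <- t_es_frac + e_len
  v_after_e <- v_ref - e_frac_la * amp
  refill <- 0.08 * amp
  v <- numeric(length(phi))
  s <- phi < p1
  v[s] <- vmin + amp * (1 - cos(pi * phi[s] / p1)) / 2
  s <- phi >= p1 & phi < p2
  v[s] <- v_ref - e_frac_la * amp *
    (1 - cos(pi * (phi[s] - p1) / (p2 - p1))) / 2
  s <- phi >= p2 & phi < t_dia_end
  v[s] <- v_after_e + refill *
    (1 - cos(pi * (phi[s] - p2) / (t_dia_end - p2))) / 2
  s <- phi >= t_dia_end & phi < t_a_end
  v[s] <- (v_after_e + refill) - (v_after_e + refill - vmin) *
    (1 - cos(pi * (phi[s] - t_dia_end) / (t_a_end - t_dia_end))) / 2
  s <- phi >= t_a_end
  v[s] <- vmin
  v
}

#' Generate the periodic wall-motion frame sequence
#'
#' Samples the chamber volume curves at `n_frames` uniformly spaced times per
#' heartbeat and computes, for each frame, the wall displacement field (with
#' respect to the end-systolic reference configuration) whose induced cavity
#' volumes match the curves. Vertex positions are linear in the two motion
#' amplitudes, so each chamber volume is an exact cubic polynomial in its
#' amplitude; the calibration solves that cubic, making the frame volumes
#' match the targets to machine precision.
#'
#' @param geom an [generate_anatomy()] geometry (the end-systolic reference).
#' @param params the matching [lh_scenario()].
#' @return an object of class `lh_motion`: boundary vertex indices, the
#'   per-frame boundary displacement array (`n_boundary x 3 x n_frames`),
#'   frame times, the reference frame index, the amplitude series, and an
#'   evaluator `disp_at(pts, frame)` for arbitrary points.
#' @export
generate_motion <- function(geom, params = geom$params) {
  stopifnot(inherits(geom, "lh_geometry"))
  mesh <- geom$mesh
  amp <- motion_amplitudes(mesh, geom$cell_region, geom, params)
  n <- params$n_frames
  T <- params$period_T
  times <- amp$times
  k_ref <- amp$k_ref
  amp_lv <- amp$amp_lv
  amp_la <- amp$amp_la
  v_lv <- amp$v_lv
  v_la <- amp$v_la

  bnodes <- sort(unique(as.vector(mesh$faces)))
  bb <- motion_basis(geom, mesh$points[bnodes, , drop = FALSE])
  frames <- array(0, c(length(bnodes), 3L, n))
  for (i in seq_len(n)) {
    frames[, , i] <- amp_lv[i] * bb$g_lv + amp_la[i] * bb$g_la
  }

  # displacement-magnitude bound (mesh validity contract)
  max_disp <- max(sqrt(apply(frames^2, c(1, 3), sum)))
  bound <- geom$shape$max_disp_frac * geom$dims$c
  if (max_disp > bound) {
    stop(sprintf(
      "wall displacement %.1f mm exceeds %.0f%% of the chamber radius; ",
      1e3 * max_disp, 100 * geom$shape$max_disp_frac),
      "reduce the ejection fraction or enlarge max_disp_frac")
  }

  structure(list(
    bnodes = bnodes, frames = frames, frame_times = times,
    period_T = T, n_frames = n, reference_frame = k_ref,
    amp_lv = amp_lv, amp_la = amp_la,
    v_lv_target = v_lv, v_la_target = v_la,
    disp_at = function(pts, frame) {
      bs <- motion_basis(geom, pts)
      amp_lv[frame] * bs$g_lv + amp_la[frame] * bs$g_la
    }
  ), class = "lh_motion")
}

# Frame-by-frame motion amplitude calibration. `geom_like` needs only
# `dims`, `shape` and `static_dist` (so the mesher can call this before the
# full geometry annotation exists).
#' @keywords internal
motion_amplitudes <- function(mesh, region, geom_like, params) {
  n <- params$n_frames
  T <- params$period_T
  times <- (seq_len(n) - 1) * T / n
  phis <- times / T
  k_ref <- which.min(abs(phis - params$t_es_frac))
  if (abs(phis[k_ref] - params$t_es_frac) > 1e-9) {
    stop("t_es_frac must lie on the frame grid (it is snapped by lh_scenario)")
  }
  vols <- tet_geom_cpp(mesh$points, mesh$tets)$vol
  esv <- sum(vols[region == 1L])
  edv <- esv / (1 - params$ejection_fraction)
  v_lv <- lv_volume_curve(phis, edv, esv, params$t_es_frac)
  v_la_ref <- sum(vols[region == 2L])
  v_la <- la_volume_curve(phis, v_la_ref, params$la_ef, params$t_es_frac)

  basis <- motion_basis(geom_like, mesh$points)
  lv_surf <- region_closed_surface(mesh, region == 1L)
  la_surf <- region_closed_surface(mesh, region == 2L)

  # vertex positions are linear in each amplitude, so chamber volumes are
  # exact cubics in it: fit once, solve per frame
  fit_cubic <- function(vol_fn, lo, hi) {
    ss <- seq(lo, hi, length.out = 4)
    vv <- vapply(ss, vol_fn, numeric(1))
    solve(outer(ss, 0:3, "^"), vv)
  }
  solve_amp <- function(co, target, lo, hi, what) {
    r <- polyroot(c(co[1] - target, co[2:4]))
    r <- Re(r)[abs(Im(r)) < 1e-7 * pmax(1, abs(Re(r)))]
    r <- r[r >= lo - 1e-9 & r <= hi + 1e-9]
    if (length(r) == 0L) {
      stop("requested ", what, " unreachable by the wall-motion ",
           "parameterization")
    }
    r[which.min(abs(r))]
  }
  co_lv <- fit_cubic(function(b) {
    surface_enclosed_volume(mesh$points + b * basis$g_lv, lv_surf)
  }, -0.45, 0.9)
  amp_lv <- vapply(v_lv, function(vt) {
    solve_amp(co_lv, vt, -0.45, 0.9, "ejection fraction")
  }, numeric(1))
  # the LA volume also feels the LV basis in the blend zone: calibrate the
  # LA amplitude per frame given the already-fixed LV amplitude
  amp_la <- vapply(seq_len(n), function(i) {
    co <- fit_cubic(function(b) {
      surface_enclosed_volume(mesh$points + amp_lv[i] * basis$g_lv +
                                b * basis$g_la, la_surf)
    }, -0.4, 0.5)
    solve_amp(co, v_la[i], -0.4, 0.5, "atrial emptying fraction")
  }, numeric(1))
  amp_lv[k_ref] <- 0
  amp_la[k_ref] <- 0
  list(times = times, k_ref = k_ref, amp_lv = amp_lv, amp_la = amp_la,
       v_lv = v_lv, v_la = v_la)
}

#' Cavity volumes induced by the motion frames
#'
#' Recomputes, by the divergence theorem over the displaced closed region
#' surface, the LV (or LA) cavity volume of each motion frame.
#'
#' @param geom the geometry.
#' @param motion the [generate_motion()] result.
#' @param region `"LV"` or `"LA"`.
#' @return numeric vector of per-frame volumes, m^3.
#' @export
frame_volumes <- function(geom, motion, region = c("LV", "LA")) {
  region <- match.arg(region)
  code <- if (region == "LV") 1L else 2L
  surf <- region_closed_surface(geom$mesh, geom$cell_region == code)
  vapply(seq_len(motion$n_frames), function(i) {
    pts <- geom$mesh$points
    pts[motion$bnodes, ] <- pts[motion$bnodes, , drop = FALSE] +
      motion$frames[, , i]
    surface_enclosed_volume(pts, surf)
  }, numeric(1))
}
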