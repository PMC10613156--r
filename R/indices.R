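# Wall shear stress and its derived stagnation indices, bulk flow metrics,
# and the clinical helper arithmetic (body surface area, heartbeat periods,
# phase fractions, echo-Doppler discrepancies).

#' Map boundary faces to their owner tetrahedra
#'
#' @param mesh a `tet_mesh`.
#' @return integer vector: for each boundary face, the index of the unique
#'   tetrahedron containing it.
#' @keywords internal
wall_face_tets <- function(mesh) {
  tets <- mesh$tets
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
  owner <- rep(seq_len(nrow(tets)), 4L)
  key3 <- function(f) {
    s1 <- pmin(f[, 1], f[, 2], f[, 3]); s3 <- pmax(f[, 1], f[, 2], f[, 3])
    s2 <- as.numeric(f[, 1]) + f[, 2] + f[, 3] - s1 - s3
    nv <- max(f) + 1
    (s1 * nv + s2) * nv + s3
  }
  m <- match(key3(mesh$faces), key3(f))
  owner[m]
}

#' Wall shear stress field
#'
#' The tangential part of the viscous traction
#' `t = mu_eff (grad u + grad u^T) n` on each wall face, using the velocity
#' gradient of the adjacent tetrahedron. Rigid-body motion of fluid and wall
#' together has a symmetric-gradient of zero and hence zero WSS.
#'
#' @param u nodal velocity, m/s.
#' @param coords current vertex coordinates, m.
#' @param mesh the `tet_mesh`.
#' @param faces wall faces (subset of `mesh$faces`), outward oriented.
#' @param face_tets owner tets of `faces` (from [wall_face_tets()]).
#' @param mu dynamic viscosity, Pa s (optionally per-element effective
#'   viscosity including the subgrid part).
#' @return `F x 3` matrix of WSS vectors, Pa.
#' @export
wall_shear_stress <- function(u, coords, mesh, faces, face_tets, mu) {
  g <- tet_geom_cpp(coords, mesh$tets)
  gr <- elem_velocity_grad_cpp(mesh$tets, g$grads, u)
  fg <- face_geometry(coords, faces)
  nrm <- fg$normal
  mu_f <- if (length(mu) > 1) mu[face_tets] else mu
  G <- gr[face_tets, , drop = FALSE]
  # traction of the symmetric gradient: t_a = mu (G[a,b] + G[b,a]) n_b
  tr <- cbind(
    mu_f * ((2 * G[, 1]) * nrm[, 1] + (G[, 2] + G[, 4]) * nrm[, 2] +
              (G[, 3] + G[, 7]) * nrm[, 3]),
    mu_f * ((G[, 4] + G[, 2]) * nrm[, 1] + (2 * G[, 5]) * nrm[, 2] +
              (G[, 6] + G[, 8]) * nrm[, 3]),
    mu_f * ((G[, 7] + G[, 3]) * nrm[, 1] + (G[, 8] + G[, 6]) * nrm[, 2] +
              (2 * G[, 9]) * nrm[, 3])
  )
  tn <- rowSums(tr * nrm)
  tr - tn * nrm
}

#' Time-averaged wall shear stress
#'
#' `TAWSS(x) = (1/T) int_0^T |WSS(x, t)| dt`, evaluated as the mean of the
#' magnitude over the uniformly spaced phase samples.
#'
#' @param wss `F x 3 x phases` array of WSS vectors, Pa.
#' @return TAWSS per face, Pa.
#' @export
tawss <- function(wss) {
  if (length(dim(wss)) != 3L || dim(wss)[3] < 1) {
    stop("empty WSS series")
  }
  mag <- sqrt(apply(wss^2, c(1, 3), sum))
  rowMeans(mag)
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |int WSS dt| / int |WSS| dt)`, in `[0, 0.5]`: 0 for
#' unidirectional shear, 0.5 for perfectly reversing shear; defined as 0
#' where the integrated magnitude vanishes.
#'
#' @param wss `F x 3 x phases` array, Pa.
#' @return OSI per face.
#' @export
osi <- function(wss) {
  mag <- sqrt(apply(wss^2, c(1, 3), sum))
  den <- rowMeans(mag)
  num <- sqrt(rowSums(apply(wss, c(1, 2), mean)^2))
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time
#'
#' `RRT = 1 / ((1 - 2 OSI) TAWSS)`, a surrogate for near-wall stagnation;
#' flagged infinite where the denominator is at or below `tol`.
#'
#' @param tawss_field TAWSS per face, Pa.
#' @param osi_field OSI per face.
#' @param tol denominator tolerance, Pa.
#' @return RRT per face, 1/Pa (`Inf` where stagnant).
#' @export
rrt <- function(tawss_field, osi_field, tol = 1e-12) {
  den <- (1 - 2 * osi_field) * tawss_field
  ifelse(den > tol, 1 / den, Inf)
}

#' Area fraction above a threshold
#'
#' Area-weighted percentage of a wall region where a face field exceeds a
#' threshold.
#'
#' @param field per-face values.
#' @param threshold threshold on `field`.
#' @param areas per-face areas, m^2.
#' @param region_mask logical mask of the faces belonging to the region.
#' @return percentage in `[0, 100]`.
#' @export
area_fraction_above <- function(field, threshold, areas,
                                region_mask = rep(TRUE, length(field))) {
  if (!any(region_mask)) stop("unknown or empty wall region")
  a <- areas[region_mask]
  100 * sum(a[field[region_mask] > threshold]) / sum(a)
}

#' E-wave propagation index
#'
#' Ratio of the distance travelled by the early-diastolic mitral jet to the
#' ventricular long-axis length: `EPI = int_Ewave (Q_MV / A_MV) dt / L`.
#' The E-wave window is the first contiguous interval after aortic valve
#' closure during which the mitral flow exceeds 5% of its diastolic peak.
#' Values below 1 indicate an incomplete apical washout.
#'
#' @param q_mv mitral flow-rate series (positive = filling), m^3/s.
#' @param times sample times, s.
#' @param orifice_area mitral orifice area, m^2.
#' @param lv_length ventricular long-axis length at end diastole, m.
#' @param t_av_close aortic valve closure time, s (start of the search).
#' @return EPI (dimensionless), with the detected window as attributes.
#' @export
epi <- function(q_mv, times, orifice_area, lv_length, t_av_close = 0) {
  stopifnot(length(q_mv) == length(times), orifice_area > 0, lv_length > 0)
  cand <- times >= t_av_close
  if (!any(cand & q_mv > 0)) stop("no diastolic forward mitral flow found")
  qpk <- max(q_mv[cand])
  inwin <- cand & q_mv > 0.05 * qpk
  # first contiguous block
  starts <- which(inwin & !c(FALSE, inwin[-length(inwin)]))
  i0 <- starts[1]
  i1 <- i0
  while (i1 < length(inwin) && inwin[i1 + 1]) i1 <- i1 + 1
  idx <- i0:i1
  dtv <- diff(times)
  dtv <- c(dtv, dtv[length(dtv)])
  dist <- sum((q_mv[idx] / orifice_area) * dtv[idx])
  out <- dist / lv_length
  attr(out, "window") <- c(times[i0], times[i1])
  out
}

#' Volume-averaged pressure in a probe sphere
#'
#' @param p nodal pressure, Pa.
#' @param coords vertex coordinates, m.
#' @param tets tetrahedra.
#' @param center,radius probe sphere, m.
#' @return mean pressure over the cells whose centroid lies in the sphere,
#'   volume weighted, Pa.
#' @export
pressure_probe <- function(p, coords, tets, center, radius) {
  g <- tet_geom_cpp(coords, tets)
  cen <- (coords[tets[, 1], ] + coords[tets[, 2], ] +
            coords[tets[, 3], ] + coords[tets[, 4], ]) / 4
  inside <- sqrt(rowSums(sweep(cen, 2, center)^2)) < radius
  if (!any(inside)) stop("probe sphere does not intersect the mesh")
  pc <- rowMeans(matrix(p[tets[inside, , drop = FALSE]], ncol = 4))
  sum(pc * g$vol[inside]) / sum(g$vol[inside])
}

#' Du Bois body surface area
#'
#' `BSA = 0.007184 * height_cm^0.725 * weight_kg^0.425`, reported to two
#' decimals.
#'
#' @param height_m height, m.
#' @param weight_kg weight, kg.
#' @return BSA, m^2 (rounded to 2 decimals).
#' @examples
#' bsa_du_bois(1.93, 84) # 2.14
#' @export
bsa_du_bois <- function(height_m, weight_kg) {
  if (any(height_m <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  round(0.007184 * (100 * height_m)^0.725 * weight_kg^0.425, 2)
}

#' Heartbeat period from the heart rate
#'
#' @param bpm heart rate, beats/min.
#' @return period `60 / bpm`, s, reported to one decimal.
#' @examples
#' heartbeat_period(66) # 0.9
#' @export
heartbeat_period <- function(bpm) {
  if (any(bpm <= 0)) stop("heart rate must be positive")
  round(60 / bpm, 1)
}

#' Relative discrepancy against a reference measurement
#'
#' `|reference - computed| / reference * 100`, reported to one decimal.
#'
#' @param reference,computed values in the same units (reference nonzero).
#' @return percentage (1 decimal).
#' @examples
#' relative_discrepancy(1.25, 1.20) # 4.0
#' @export
relative_discrepancy <- function(reference, computed) {
  if (any(reference == 0)) stop("zero reference value")
  round(abs(reference - computed) / reference * 100, 1)
}

#' Cardiac phase fraction of an event
#'
#' `100 t_event / T`, rounded to the nearest integer percent.
#'
#' @param t_event event time within the cycle, s.
#' @param T cycle period, s.
#' @return percentage (integer).
#' @examples
#' phase_fraction(0.32, 0.8) # 40
#' @export
phase_fraction <- function(t_event, T) {
  if (any(t_event < 0) || any(t_event > T)) {
    stop("event time outside the cycle")
  }
  round(100 * t_event / T)
}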