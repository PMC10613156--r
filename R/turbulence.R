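# Phase-locked ensemble statistics over retained heartbeats: mean and
# standard-deviation fields, Reynolds stresses, maximum tangential stress
# with hemolysis exposure metrics, chamber-integrated turbulent kinetic
# energy, and the Pope LES-quality criterion.

#' Build a cycle stack from a run
#'
#' Collects the phase-locked velocity and subgrid-viscosity snapshots of the
#' retained cycles together with the mesh/label information needed by the
#' ensemble statistics.
#'
#' @param run an `lh_run` from [run_cycles()].
#' @param geom the matching geometry.
#' @return a `cycle_stack` list.
#' @export
cycle_stack <- function(run, geom) {
  stopifnot(inherits(run, "lh_run"), inherits(geom, "lh_geometry"))
  cellvol <- lapply(run$phase_coords, function(cc) {
    tet_geom_cpp(cc, geom$mesh$tets)$vol
  })
  structure(list(
    u = run$u_snap, musgs = run$musgs_snap,
    n = dim(run$u_snap)[4], m = run$n_phases,
    phase_times = run$phase_times, phase_coords = run$phase_coords,
    cell_volumes = cellvol, tets = geom$mesh$tets,
    cell_region = geom$cell_region, apex_cells = geom$apex_cells,
    laa_cells = geom$laa_cells, period_T = run$geom_params$period_T
  ), class = "cycle_stack")
}

#' Phase-locked ensemble mean and standard deviation
#'
#' The ensemble mean is the arithmetic average over the retained cycles at
#' each vertex, component and phase. Second moments use the population
#' estimator (divide by n), matching the Reynolds-stress definition; the SD
#' field is reported as the component-wise RMS magnitude
#' `sqrt(sum_i <u_i' u_i'>)`.
#'
#' @param stack a [cycle_stack()] (or a plain `[node, comp, phase, cycle]`
#'   array).
#' @return an `ensemble_stats` list: `mean` (`n x 3 x phases`), `var`
#'   (per-component population variances, `n x 3 x phases`), `sd_mag`
#'   (`n x phases`).
#' @export
ensemble_stats <- function(stack) {
  u <- if (inherits(stack, "cycle_stack")) stack$u else stack
  dm <- dim(u)
  if (length(dm) != 4L) stop("expected a [node, comp, phase, cycle] array")
  if (dm[4] < 2L) stop("at least 2 retained cycles are needed for the SD")
  flat <- matrix(u, prod(dm[1:3]), dm[4])
  mu <- rowMeans(flat)
  va <- rowMeans(flat^2) - mu^2
  va[va < 0] <- 0 # numerical floor
  mean_arr <- array(mu, dm[1:3])
  var_arr <- array(va, dm[1:3])
  sd_mag <- sqrt(apply(var_arr, c(1, 3), sum))
  structure(list(mean = mean_arr, var = var_arr, sd_mag = sd_mag,
                 n = dm[4]), class = "ensemble_stats")
}

#' Reynolds stress tensor field
#'
#' `R_ij = rho <u_i' u_j'>` with the population (divide by n) ensemble
#' covariance at each vertex and phase; symmetric positive semidefinite.
#'
#' @param stack a [cycle_stack()] or `[node, comp, phase, cycle]` array.
#' @param rho density, kg/m^3.
#' @return a `reynolds_stress` list: `comp`, an `n x 6 x phases` array in
#'   the order (xx, yy, zz, xy, xz, yz), Pa; and `rho`.
#' @export
reynolds_stress <- function(stack, rho = 1060) {
  u <- if (inherits(stack, "cycle_stack")) stack$u else stack
  dm <- dim(u)
  if (dm[4] < 2L) stop("at least 2 retained cycles are needed")
  nc <- dm[4]
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  out <- array(0, c(dm[1], 6L, dm[3]))
  for (k in 1:6) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    xa <- matrix(u[, a, , ], dm[1] * dm[3], nc)
    xb <- matrix(u[, b, , ], dm[1] * dm[3], nc)
    cov <- rowMeans(xa * xb) - rowMeans(xa) * rowMeans(xb)
    out[, k, ] <- rho * cov
  }
  structure(list(comp = out, rho = rho), class = "reynolds_stress")
}

#' Maximum tangential (principal shear) stress
#'
#' The largest shear stress sustainable across any plane:
#' `tau_max = (lambda_max - lambda_min) / 2` of the (symmetric) Reynolds
#' stress tensor at each point and phase, computed with the closed-form
#' trigonometric eigenvalue formula for symmetric 3x3 tensors.
#'
#' @param R a `reynolds_stress`, an `n x 6` / `n x 6 x phases` component
#'   array (xx, yy, zz, xy, xz, yz), or a single symmetric 3x3 matrix.
#' @return tau_max, Pa, with the shape of the input minus the component
#'   axis; always >= 0.
#' @examples
#' tau_max(diag(c(1600, 0, 0))) # 800
#' @export
tau_max <- function(R) {
  if (inherits(R, "reynolds_stress")) R <- R$comp
  if (is.matrix(R) && nrow(R) == 3 && ncol(R) == 3) {
    if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R)))) {
      stop("tau_max requires a symmetric tensor")
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    return((max(ev) - min(ev)) / 2)
  }
  dm <- dim(R)
  flat <- if (length(dm) == 3L) matrix(R, dm[1] * dm[3], 6) else R
  a11 <- flat[, 1]; a22 <- flat[, 2]; a33 <- flat[, 3]
  a12 <- flat[, 4]; a13 <- flat[, 5]; a23 <- flat[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  tm <- (e1 - e3) / 2
  if (length(dm) == 3L) array(tm, c(dm[1], dm[3])) else tm
}

#' Hemolysis exposure metrics
#'
#' From a `tau_max` field sampled on the phase grid: `D(x)`, the fraction of
#' the cycle during which `tau_max > threshold` at each point;
#' `volume_above(t)`, the volume exposed at each phase; and the total
#' exposure time, the measure of phase instants at which any point exceeds
#' the threshold.
#'
#' @param tau `n x phases` matrix of tau_max, Pa.
#' @param threshold hemolysis threshold, Pa (default 800).
#' @param T cycle period, s.
#' @param volumes integration weights per row of `tau` (cell volumes or
#'   lumped nodal volumes), m^3; a single phase-independent vector or an
#'   `n x phases` matrix.
#' @return an `exposure_report` list: `D`, `volume_above`,
#'   `total_exposure_time` (s), `threshold`.
#' @export
exposure_metrics <- function(tau, threshold = 800, T, volumes) {
  tau <- as.matrix(tau)
  m <- ncol(tau)
  above <- tau > threshold
  D <- rowMeans(above)
  if (is.matrix(volumes)) {
    volume_above <- colSums(above * volumes)
  } else {
    volume_above <- as.numeric(crossprod(volumes, above))
  }
  total <- sum(colSums(above) > 0) * (T / m)
  structure(list(D = D, volume_above = volume_above,
                 total_exposure_time = total, threshold = threshold),
            class = "exposure_report")
}

#' Global turbulent kinetic energy of a chamber
#'
#' `GTKE(t) = int_region 0.5 rho sum_i <u_i' u_i'> dV`, the volume-integrated
#' resolved fluctuating kinetic energy, per phase.
#'
#' @param stats an [ensemble_stats()].
#' @param stack the [cycle_stack()] carrying mesh, labels and per-phase cell
#'   volumes.
#' @param region `"LV"`, `"LA"`, `"AR"`, `"LV_apex"` or `"LAA"`.
#' @param rho density, kg/m^3.
#' @return GTKE per phase, J.
#' @export
gtke <- function(stats, stack, region = c("LV", "LA", "AR", "LV_apex", "LAA"),
                 rho = 1060) {
  region <- match.arg(region)
  cells <- switch(region,
    LV = stack$cell_region == 1L, LA = stack$cell_region == 2L,
    AR = stack$cell_region == 3L, LV_apex = stack$apex_cells,
    LAA = stack$laa_cells)
  if (!any(cells)) stop("unknown or empty region: ", region)
  tets <- stack$tets[cells, , drop = FALSE]
  m <- stack$m
  out <- numeric(m)
  for (ph in seq_len(m)) {
    k_nodal <- rowSums(stats$var[, , ph]) # sum of component variances
    k_cell <- rowMeans(matrix(k_nodal[tets], ncol = 4))
    out[ph] <- 0.5 * rho * sum(stack$cell_volumes[[ph]][cells] * k_cell)
  }
  out
}

#' Pope LES-quality criterion
#'
#' `M(x, t) = k_sgs / (k_sgs + k_res)` with
#' `k_sgs = (mu_sgs / (C Delta rho))^2` the subgrid turbulent kinetic energy
#' and `k_res = 0.5 sum_i <u_i' u_i'>` the resolved fluctuating kinetic
#' energy (phase-resolved, averaged over cycles for `mu_sgs`). `M` is 0
#' where both vanish. Values below 0.2 mark well-resolved LES regions; the
#' returned fraction is cell-volume weighted.
#'
#' @param stats an [ensemble_stats()].
#' @param stack a [cycle_stack()].
#' @param c_les LES constant.
#' @param delta filter width, m.
#' @param rho density, kg/m^3.
#' @param m_threshold quality threshold on M.
#' @return list: `M` (`cells x phases`), `fraction_below` per phase, and
#'   `mean_fraction_below` (time average).
#' @export
pope_criterion <- function(stats, stack, c_les = 1.5, delta, rho = 1060,
                           m_threshold = 0.2) {
  m <- stack$m
  mu_mean <- apply(stack$musgs, c(1, 2), mean) # cycle-averaged mu_sgs
  k_sgs <- (mu_mean / (c_les * delta * rho))^2
  tets <- stack$tets
  Mf <- matrix(0, nrow(tets), m)
  frac <- numeric(m)
  for (ph in seq_len(m)) {
    k_nodal <- 0.5 * rowSums(stats$var[, , ph])
    k_res <- rowMeans(matrix(k_nodal[tets], ncol = 4))
    tot <- k_sgs[, ph] + k_res
    Mf[, ph] <- ifelse(tot > 0, k_sgs[, ph] / tot, 0)
    vol <- stack$cell_volumes[[ph]]
    frac[ph] <- sum(vol[Mf[, ph] < m_threshold]) / sum(vol)
  }
  list(M = Mf, fraction_below = frac, mean_fraction_below = mean(frac))
}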