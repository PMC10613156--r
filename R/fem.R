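# Incompressible ALE Navier-Stokes core: P1 tetrahedral finite elements with
# an incremental pressure-correction (fractional-step) scheme.
#
# Per step, on the moved mesh:
#   1. momentum predictor: implicit lumped mass / diffusion (mu + mu_sgs +
#      streamline artificial viscosity) / lumped resistive valve penalty,
#      explicit convection with the ALE-relative velocity (u - u_ALE) and the
#      old pressure gradient; SPD systems with penalty Dirichlet rows so the
#      sparse Cholesky symbolic factorization is reused across steps;
#   2. pressure Poisson for the increment with Dirichlet values at the open
#      boundaries (the prescribed normal stress) and natural conditions at
#      walls, then a lumped-mass projection; optional extra correction
#      sweeps reusing the same factorization tighten the divergence.
# Velocity Dirichlet data: the wall moves with the domain (u = wall
# velocity); at the open boundaries the tangential (in-plane) velocity is
# set to zero and the normal component is free.

#' Fluid properties
#'
#' @param density blood density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return a `fluid_properties` list.
#' @export
fluid_properties <- function(density = 1060, viscosity = 3.5e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Flow solver configuration
#'
#' @param dt time step, s.
#' @param c_sigma sigma-model constant.
#' @param delta LES filter width, m; defaults to the mesh spacing.
#' @param use_les enable the sigma-model subgrid viscosity.
#' @param c_stab streamline (first-order upwind type) artificial viscosity
#'   coefficient; the added viscosity is `c_stab * 0.5 * rho * |u - u_ALE| * h`
#'   per element.
#' @param n_projection pressure-correction sweeps per step (>= 1).
#' @param div_tol advisory RMS divergence tolerance (s^-1) used by
#'   diagnostics.
#' @param cfl_warn CFL number above which a warning is recorded.
#' @param refactor_every numeric refactorization interval of the Cholesky
#'   factors (the matrices drift slowly with the mesh motion; intermediate
#'   steps reuse the last factorization as a preconditioner with iterative
#'   refinement against the current matrix).
#' @param p_filter blending weight of the per-step neighbour-average
#'   pressure filter that suppresses the node-to-node pressure mode of the
#'   equal-order velocity/pressure pair (0 disables).
#' @param p_stab scaled-Laplacian pressure stabilization weight added to the
#'   dual projection operator (removes its spurious-mode kernel).
#' @return a `solver_config` list.
#' @export
solver_config <- function(dt = 5e-4, c_sigma = 1.5, delta = NULL,
                          use_les = TRUE, c_stab = 0.5, n_projection = 1L,
                          div_tol = 5, cfl_warn = 1.0, refactor_every = 6L,
                          p_filter = 0.3, p_stab = 0.1) {
  stopifnot(dt > 0, c_sigma > 0, n_projection >= 1, refactor_every >= 1,
            p_filter >= 0, p_filter <= 1, p_stab > 0)
  structure(list(dt = dt, c_sigma = c_sigma, delta = delta,
                 use_les = use_les, c_stab = c_stab,
                 n_projection = as.integer(n_projection),
                 div_tol = div_tol, cfl_warn = cfl_warn,
                 refactor_every = as.integer(refactor_every),
                 p_filter = p_filter, p_stab = p_stab),
            class = "solver_config")
}

#' Set up a flow problem on a tetrahedral mesh
#'
#' Precomputes the sparsity pattern, Dirichlet masks, and symbolic Cholesky
#' factorizations reused by every time step.
#'
#' @param mesh a `tet_mesh`.
#' @param wall_nodes vertex indices with full velocity Dirichlet data.
#' @param open_nodes vertex indices on open (pressure) boundaries: pressure
#'   Dirichlet, in-plane velocity zero, normal (z) velocity free.
#' @param open_faces outward-oriented boundary triangles of the open
#'   patches; the prescribed normal stress enters the momentum equation
#'   through the boundary integral over these faces.
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @return a `flow_problem` environment.
#' @export
flow_setup <- function(mesh, wall_nodes, open_nodes, open_faces = NULL,
                       props = fluid_properties(),
                       config = solver_config()) {
  n <- nrow(mesh$points)
  pr <- new.env(parent = emptyenv())
  pr$mesh <- mesh
  pr$n <- n
  pr$tets <- mesh$tets
  pr$props <- props
  pr$config <- config
  if (is.null(config$delta)) pr$config$delta <- mesh$h
  pr$wall_nodes <- wall_nodes
  pr$open_nodes <- open_nodes
  pr$open_faces <- open_faces
  pr$dir_xy <- sort(unique(c(wall_nodes, open_nodes)))
  pr$dir_z <- sort(unique(wall_nodes))
  pr$pat <- sparse_pattern(mesh$tets, n)
  pr$idx_scatter <- as.vector(mesh$tets)
  # symbolic factorizations from a representative assembly
  g <- tet_geom_cpp(mesh$points, mesh$tets)
  ml <- lumped_mass_cpp(mesh$tets, g$vol, n)
  sv <- stiffness_vals_cpp(g$vol, g$grads, rep(props$viscosity, nrow(mesh$tets)))
  dvec <- props$density / config$dt * ml
  A <- fill_sym(pr$pat, sv, diag_add = dvec)
  pr$chol_xy <- Matrix::Cholesky(A, LDL = FALSE)
  pr$chol_z <- Matrix::Cholesky(A, LDL = FALSE)
  pr$step_count <- 0L
  pr$adj <- vertex_adjacency(mesh$tets, n)
  class(pr) <- c("flow_problem", "environment")
  pr
}

# one pass of neighbour-average filtering (removes the node-to-node pressure
# mode of the equal-order pair; alpha blends with the unfiltered field)
.filter_nodal <- function(f, adj, alpha) {
  acc <- rowsum(f[adj$edges[, 2]], adj$edges[, 1], reorder = TRUE)
  avg <- f
  avg[adj$idx] <- acc / pmax(adj$deg[adj$idx], 1L)
  (1 - alpha) * f + alpha * avg
}

# Preconditioned Richardson iteration: x_{k+1} = x_k + P^-1 (b - A x_k).
# Used for the projection solve with A the pure dual operator and P the
# factorized stabilized operator: the velocity-relevant (range) subspace
# contracts geometrically (factor ~ alpha), while the checkerboard kernel
# neither converges nor grows -- and its correction through G^T is zero, so
# it never reaches the velocity.
.prichardson <- function(matvec, b, prec, iters = 5L) {
  x <- prec(b)
  for (it in seq_len(iters)) {
    x <- x + prec(b - matvec(x))
  }
  x
}

# solve with a possibly stale Cholesky factor, refined against the current
# matrix (one refinement sweep; exact when the factor is fresh)
.solve_refined <- function(chol, A, b, fresh) {
  x <- as.numeric(Matrix::solve(chol, b, system = "A"))
  if (fresh) return(x)
  r <- b - as.numeric(A %*% x)
  x + as.numeric(Matrix::solve(chol, r, system = "A"))
}

#' Initialize a flow state
#'
#' @param problem a `flow_problem`.
#' @return a `flow_state` list with zero velocity and pressure (the null
#'   initial condition).
#' @export
flow_state_init <- function(problem) {
  structure(list(
    u = matrix(0, problem$n, 3), p = numeric(problem$n),
    mu_sgs = numeric(nrow(problem$tets)), t = 0,
    div_rms = 0, cfl = 0
  ), class = "flow_state")
}

# scatter per-element values (times V/4) to nodes
.scatter_nodes <- function(tets, w, n) {
  acc <- rowsum(rep(w, 4), as.vector(tets), reorder = TRUE)
  out <- numeric(n)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' sigma-model subgrid viscosity
#'
#' Computes the sigma-model eddy viscosity from element-wise velocity
#' gradients: with singular values `s1 >= s2 >= s3 >= 0` of the 3x3 velocity
#' gradient, the differential operator is
#' `D = s3 (s1 - s2) (s2 - s3) / s1^2` (zero for `s1 = 0`) and
#' `mu_sgs = rho (C_sigma Delta)^2 D`. The operator vanishes identically for
#' two-component (planar) flows, rank-deficient gradients and solid-body
#' rotation.
#'
#' @param grad element velocity gradients: `M x 9` matrix, row layout
#'   `(du1/dx1, du1/dx2, ..., du3/dx3)`, s^-1.
#' @param delta filter width, m.
#' @param rho density, kg/m^3.
#' @param c_sigma model constant.
#' @return `mu_sgs` per element, Pa s.
#' @examples
#' g <- matrix(0, 1, 9); g[1, c(1, 5, 9)] <- c(3, 2, 1)
#' sigma_subgrid_viscosity(g, 1e-3, 1060, 1.5) # ~2.65e-4
#' @export
sigma_subgrid_viscosity <- function(grad, delta, rho, c_sigma = 1.5) {
  stopifnot(delta > 0, rho > 0, c_sigma > 0)
  if (!all(is.finite(grad))) stop("non-finite velocity gradient entries")
  rho * (c_sigma * delta)^2 * sigma_dsigma_cpp(as.matrix(grad))
}

#' Advance the flow one time step
#'
#' @param problem a `flow_problem`.
#' @param state the current `flow_state`.
#' @param coords vertex coordinates of the (already moved) mesh at the new
#'   time, m.
#' @param u_ale ALE mesh velocity at every vertex (`n x 3`), m/s.
#' @param wall_values velocity Dirichlet data at `wall_nodes`, m/s.
#' @param p_bc pressure Dirichlet values at `open_nodes`, Pa.
#' @param riis_diag lumped resistive valve penalty per node
#'   (`R_Gamma / eps_Gamma * delta_Gamma`, 1/s times density scale), kg/(m^3 s);
#'   zero vector if no valve is active near a node.
#' @param t_new new time, s.
#' @return the updated `flow_state`.
#' @export
advance_time_step <- function(problem, state, coords, u_ale, wall_values,
                              p_bc, riis_diag = NULL, t_new = state$t +
                                problem$config$dt) {
  pr <- problem
  cfg <- pr$config
  props <- pr$props
  n <- pr$n
  tets <- pr$tets
  dt <- cfg$dt
  rho <- props$density
  if (is.null(riis_diag)) riis_diag <- numeric(n)

  g <- tet_geom_cpp(coords, tets)
  if (any(g$vol <= 0)) stop("moved mesh has non-positive cell volumes")
  ml <- lumped_mass_cpp(tets, g$vol, n)

  u <- state$u
  w <- u - u_ale
  gradU <- elem_velocity_grad_cpp(tets, g$grads, u)
  mu_sgs <- if (cfg$use_les) {
    sigma_subgrid_viscosity(gradU, cfg$delta, rho, cfg$c_sigma)
  } else numeric(nrow(tets))
  # element-average advecting speed for the artificial viscosity
  wmag <- sqrt(rowMeans(matrix(w[tets, 1], ncol = 4))^2 +
                 rowMeans(matrix(w[tets, 2], ncol = 4))^2 +
                 rowMeans(matrix(w[tets, 3], ncol = 4))^2)
  # streamline artificial viscosity, gated by the cell Peclet number so it
  # vanishes in diffusion-dominated (well-resolved) flow
  pe <- rho * wmag * pr$mesh$h / (2 * props$viscosity)
  mu_stab <- cfg$c_stab * 0.5 * rho * wmag * pr$mesh$h *
    pmax(0, 1 - 1 / pmax(pe, 1e-12))
  mu_eff <- props$viscosity + mu_sgs + mu_stab

  diag_base <- rho / dt * ml + riis_diag * ml
  # penalty on the inertial scale only: where the valve penalty dominates a
  # Dirichlet row it already drives the velocity to the wall/ALE value, and
  # scaling with the (huge) valve coefficient would imperil positive
  # definiteness in double precision
  pen <- 1e7 * max(rho / dt * ml)
  dxy <- numeric(n); dxy[pr$dir_xy] <- pen
  dz <- numeric(n); dz[pr$dir_z] <- pen
  xA <- stiff_fill_cpp(g$vol, g$grads, mu_eff, pr$pat$pos_sym,
                       length(pr$pat$S@x))
  xA[pr$pat$diag_sym] <- xA[pr$pat$diag_sym] + diag_base
  A_xy <- pr$pat$S
  A_z <- pr$pat$S
  xz <- xA
  xA[pr$pat$diag_sym] <- xA[pr$pat$diag_sym] + dxy
  xz[pr$pat$diag_sym] <- xz[pr$pat$diag_sym] + dz
  A_xy@x <- xA
  A_z@x <- xz
  # refactor on schedule and whenever the valve penalty field switches (the
  # matrix jumps by orders of magnitude there); the momentum factors are
  # additionally refreshed when the advecting speed scale drifts, since
  # their diffusion block follows the velocity-dependent viscosities
  wmax <- max(wmag)
  fresh <- pr$step_count %% pr$config$refactor_every == 0L ||
    !identical(pr$last_riis, riis_diag)
  fresh_mom <- fresh || is.null(pr$last_wmax) ||
    abs(wmax - pr$last_wmax) > 0.25 * max(wmax, pr$last_wmax, 1e-9)
  # the projection operator depends on the mesh only: on a static mesh its
  # factorization is reused indefinitely
  coords_sig <- c(coords[1L], coords[n], sum(coords))
  fresh_p <- is.null(pr$last_coords_sig) ||
    ((fresh || fresh_mom) && !identical(pr$last_coords_sig, coords_sig))
  if (fresh_p) pr$last_coords_sig <- coords_sig
  pr$last_riis <- riis_diag
  if (fresh_mom) pr$last_wmax <- wmax
  pr$n_fresh <- (if (is.null(pr$n_fresh)) 0L else pr$n_fresh) + fresh
  pr$n_fresh_mom <- (if (is.null(pr$n_fresh_mom)) 0L else pr$n_fresh_mom) +
    fresh_mom
  if (fresh_mom) {
    pr$chol_xy <- Matrix::update(pr$chol_xy, A_xy)
    pr$chol_z <- Matrix::update(pr$chol_z, A_z)
  }

  conv <- convection_term_cpp(tets, g$vol, g$grads, u, w)
  # pressure integrated by parts: + (p, div v) - boundary flux of the
  # prescribed normal stress over the open patches (pressure-outlet form)
  gp <- pdivv_scatter_cpp(tets, g$vol, g$grads, state$p)
  rhs <- (rho / dt) * ml * u + riis_diag * ml * u_ale - rho * conv + gp
  if (!is.null(pr$open_faces)) {
    pad <- rep(NA_real_, n)
    pad[pr$open_nodes] <- p_bc
    fmat <- pr$open_faces
    pf <- rowMeans(matrix(pad[fmat], ncol = 3), na.rm = TRUE)
    pf[!is.finite(pf)] <- 0
    fgb <- face_geometry(coords, fmat)
    wgt <- pf * fgb$area / 3
    for (c in 1:3) {
      contrib <- rowsum(rep(wgt * fgb$normal[, c], 3), as.vector(fmat),
                        reorder = TRUE)
      ids <- as.integer(rownames(contrib))
      rhs[ids, c] <- rhs[ids, c] - contrib
    }
  }
  bcv <- matrix(0, n, 3)
  bcv[pr$wall_nodes, ] <- wall_values
  # open boundaries: tangential (x, y) components pinned to zero
  rhs[, 1] <- rhs[, 1] + dxy * bcv[, 1]
  rhs[, 2] <- rhs[, 2] + dxy * bcv[, 2]
  rhs[, 3] <- rhs[, 3] + dz * bcv[, 3]
  ustar <- cbind(
    .solve_refined(pr$chol_xy, A_xy, rhs[, 1], fresh_mom),
    .solve_refined(pr$chol_xy, A_xy, rhs[, 2], fresh_mom),
    .solve_refined(pr$chol_z, A_z, rhs[, 3], fresh_mom)
  )

  # Incremental pressure correction with the consistent dual operator
  # S = sum_c G_c ML^-1 G_c^T, where G_c is the weak-divergence operator and
  # crossprod(G_c, p) the adjoint (integrated-by-parts) pressure gradient
  # used in the momentum equation. With this pairing each sweep annihilates
  # the weak divergence exactly (up to the re-imposed Dirichlet data), so
  # the sweeps converge. The light neighbour filter below keeps the
  # accumulated pressure free of the equal-order node-to-node mode.
  GX <- gdiv_fill3_cpp(g$vol, g$grads, pr$pat$pos_gen,
                       length(pr$pat$G@x))
  Gm <- lapply(1:3, function(c) {
    A <- pr$pat$G
    A@x <- GX[, c]
    A
  })
  # constrained projection: velocity corrections act only on free dofs (the
  # Dirichlet data are part of the divergence constraint, not unknowns)
  free_xy <- rep(1, n); free_xy[pr$dir_xy] <- 0
  free_z <- rep(1, n); free_z[pr$dir_z] <- 0
  Gf <- list(Gm[[1]] %*% Matrix::Diagonal(x = free_xy),
             Gm[[2]] %*% Matrix::Diagonal(x = free_xy),
             Gm[[3]] %*% Matrix::Diagonal(x = free_z))
  alpha_p <- cfg$p_stab
  # The prescribed cap pressure acts through the momentum boundary integral
  # (pressure-outlet form); the pressure equation keeps its continuity rows
  # at the caps, so global mass is conserved there too. A single node is
  # pinned to fix the pressure level (its continuity row is the only one
  # sacrificed).
  pin <- if (length(pr$open_nodes)) pr$open_nodes[1L] else 1L
  if (fresh_p) {
    # Brezzi-Pitkaranta-style stabilization: the dual operator is singular
    # on the spurious (checkerboard) pressure modes of the equal-order
    # pair; a small scaled Laplacian removes the kernel and damps them
    K1 <- fill_sym(pr$pat, stiffness_vals_cpp(g$vol, g$grads,
                                              rep(1, nrow(tets))))
    Dinv <- Matrix::Diagonal(x = 1 / ml)
    S <- Gf[[1]] %*% Dinv %*% Matrix::t(Gf[[1]]) +
      Gf[[2]] %*% Dinv %*% Matrix::t(Gf[[2]]) +
      Gf[[3]] %*% Dinv %*% Matrix::t(Gf[[3]])
    S <- methods::as(Matrix::forceSymmetric(S, "U"), "CsparseMatrix") +
      alpha_p * K1
    pen_p <- 1e7 * max(Matrix::diag(S))
    S <- S + Matrix::sparseMatrix(i = pin, j = pin, x = pen_p,
                                  dims = c(n, n), symmetric = TRUE)
    pr$chol_p <- Matrix::Cholesky(S, LDL = FALSE)
    pr$pen_p <- pen_p
  }
  pen_p <- pr$pen_p
  # Solve the *unstabilized* dual system by conjugate gradients,
  # preconditioned with the (possibly slightly stale) factorization of the
  # stabilized operator: the projection then annihilates the weak
  # divergence of the free dofs to solver tolerance, with no stabilization
  # residual, and tolerates stale factors gracefully. The checkerboard
  # kernel of S never pollutes the velocity (its correction through G^T is
  # identically zero).
  Smv <- function(x) {
    out <- numeric(n)
    for (c in 1:3) {
      out <- out + as.numeric(Gf[[c]] %*%
                                (as.numeric(Matrix::crossprod(Gf[[c]], x)) / ml))
    }
    out[pin] <- out[pin] + pen_p * x[pin]
    out
  }
  prec <- function(r) as.numeric(Matrix::solve(pr$chol_p, r, system = "A"))
  p <- state$p
  unew <- ustar
  dp_bc <- numeric(n)
  if (length(pr$open_nodes)) dp_bc[pin] <- p_bc[1L] - p[pin]
  for (sweep in seq_len(cfg$n_projection)) {
    b <- as.numeric(Gm[[1]] %*% unew[, 1] + Gm[[2]] %*% unew[, 2] +
                      Gm[[3]] %*% unew[, 3])
    rp <- -(rho / dt) * b + pen_p * dp_bc
    dp <- .prichardson(Smv, rp, prec, iters = 3L)
    for (c in 1:3) {
      unew[, c] <- unew[, c] +
        (dt / rho) * as.numeric(Matrix::crossprod(Gf[[c]], dp)) / ml
    }
    p <- p + dp
    dp_bc <- numeric(n) # later sweeps keep the boundary values
    # re-impose velocity Dirichlet data (a no-op for the constrained
    # correction; kept as a safety net)
    unew[pr$wall_nodes, ] <- wall_values
    unew[pr$open_nodes, 1:2] <- 0
  }

  # Global mass fix: cells whose four vertices all lie on the moving wall
  # carry purely prescribed (non-solenoidal) data divergence that no free
  # dof can absorb; the small resulting global mass residual is removed by
  # a uniform normal-velocity correction over the open caps, the standard
  # flux correction of prescribed-motion chamber CFD.
  if (length(pr$open_nodes)) {
    if (is.null(pr$open_wgt)) {
      fmat <- pr$open_faces
      fgb0 <- face_geometry(pr$mesh$points, fmat)
      is_open <- matrix(fmat %in% pr$open_nodes, ncol = 3)
      pr$open_wgt <- sum(fgb0$area * rowMeans(is_open) * abs(fgb0$normal[, 3]))
    }
    for (pass in 1:2) {
      r_mass <- sum(g$vol * elem_divergence_cpp(tets, g$grads, unew))
      unew[pr$open_nodes, 3] <- unew[pr$open_nodes, 3] - r_mass / pr$open_wgt
    }
  }

  if (cfg$p_filter > 0) {
    p <- .filter_nodal(p, pr$adj, cfg$p_filter)
  }

  dive <- elem_divergence_cpp(tets, g$grads, unew)
  div_rms <- sqrt(sum(g$vol * dive^2) / sum(g$vol))
  cfl <- max(wmag) * dt / pr$mesh$h
  pr$step_count <- pr$step_count + 1L
  structure(list(u = unew, p = p, mu_sgs = mu_sgs, t = t_new,
                 div_rms = div_rms, cfl = cfl), class = "flow_state")
}

#' Kinetic energy and viscous dissipation diagnostics
#'
#' `flow_kinetic_energy` returns `0.5 rho \int |u|^2 dV` (J);
#' `flow_dissipation` returns `\int mu_total |grad u|^2 dV` (W) with
#' `mu_total = mu + mu_sgs` (the subgrid viscosity may be omitted).
#'
#' @param problem a `flow_problem`.
#' @param state a `flow_state`.
#' @param coords current vertex coordinates.
#' @param include_sgs include the subgrid viscosity in the dissipation.
#' @return scalar.
#' @export
flow_kinetic_energy <- function(problem, state, coords) {
  g <- tet_geom_cpp(coords, problem$tets)
  ml <- lumped_mass_cpp(problem$tets, g$vol, problem$n)
  0.5 * problem$props$density * sum(ml * rowSums(state$u^2))
}

#' @rdname flow_kinetic_energy
#' @export
flow_dissipation <- function(problem, state, coords, include_sgs = TRUE) {
  g <- tet_geom_cpp(coords, problem$tets)
  gr <- elem_velocity_grad_cpp(problem$tets, g$grads, state$u)
  mu <- problem$props$viscosity +
    if (include_sgs) state$mu_sgs else 0
  sum(g$vol * mu * rowSums(gr^2))
}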