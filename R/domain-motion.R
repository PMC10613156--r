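# Continuous periodic boundary motion and its interior extension.
#
# The frame displacements are interpolated in time with a periodic cubic
# spline (C2, exact at the frames) and extended into the fluid volume by a
# homogeneous isotropic linear-elastic operator with optional inverse-volume
# stiffening of small cells; a harmonic extension is available as a cheaper
# fallback. The ALE mesh velocity is the first-order backward difference of
# the extended displacement, consistent with the flow solver's time stepping.

#' Periodic cubic spline through uniformly spaced samples
#'
#' Builds a C2 periodic interpolating spline through `n` samples of a
#' (possibly vector-valued) periodic signal at uniformly spaced times
#' `(i-1) * period / n`. With fewer than 4 samples the interpolation degrades
#' to periodic linear interpolation, with a warning.
#'
#' @param values `n x m` matrix: one row per sample time, one column per
#'   signal component (a vector is treated as one column).
#' @param period the period, s.
#' @return an object of class `periodic_spline`.
#' @examples
#' ps <- periodic_spline(cbind(sin(2 * pi * (0:29) / 30)), 1)
#' eval_periodic_spline(ps, 0.5)
#' @export
periodic_spline <- function(values, period) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(n >= 2, period > 0)
  if (n < 4) {
    warning("fewer than 4 frames: spline order reduced to periodic linear ",
            "interpolation")
    return(structure(list(values = values, period = period, n = n,
                          linear = TRUE), class = "periodic_spline"))
  }
  h <- period / n
  # cyclic tridiagonal system for the second derivatives
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- 4
    A[i, if (i == 1) n else i - 1] <- 1
    A[i, if (i == n) 1 else i + 1] <- 1
  }
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  rhs <- 6 * (values[im, , drop = FALSE] - 2 * values +
                values[ip, , drop = FALSE]) / h^2
  M <- solve(A, rhs)
  structure(list(values = values, M = M, period = period, n = n, h = h,
                 linear = FALSE), class = "periodic_spline")
}

#' @rdname periodic_spline
#' @param ps a `periodic_spline`.
#' @param t evaluation time, s (wrapped periodically); scalar.
#' @return numeric vector of length `m`.
#' @export
eval_periodic_spline <- function(ps, t) {
  tt <- t - floor(t / ps$period) * ps$period
  if (ps$linear) {
    h <- ps$period / ps$n
    k <- floor(tt / h)
    xi <- (tt - k * h) / h
    k1 <- (k %% ps$n) + 1L
    k2 <- (k1 %% ps$n) + 1L
    return(drop((1 - xi) * ps$values[k1, ] + xi * ps$values[k2, ]))
  }
  h <- ps$h
  k <- floor(tt / h)
  xi <- tt - k * h
  k1 <- as.integer(k %% ps$n) + 1L
  k2 <- (k1 %% ps$n) + 1L
  y1 <- ps$values[k1, ]; y2 <- ps$values[k2, ]
  m1 <- ps$M[k1, ]; m2 <- ps$M[k2, ]
  drop(y1 + xi * ((y2 - y1) / h - h * (2 * m1 + m2) / 6) +
         xi^2 * m1 / 2 + xi^3 * (m2 - m1) / (6 * h))
}

#' Continuous boundary motion from motion frames
#'
#' Wraps the frame sequence in a periodic spline; evaluation at any time
#' returns the boundary displacement field, reproducing the frames exactly
#' at the frame times.
#'
#' @param motion an [generate_motion()] result.
#' @return an object of class `continuous_motion`.
#' @export
continuous_motion <- function(motion) {
  stopifnot(inherits(motion, "lh_motion"))
  nb <- length(motion$bnodes)
  vals <- t(matrix(motion$frames, nb * 3L, motion$n_frames))
  ps <- periodic_spline(vals, motion$period_T)
  structure(list(spline = ps, bnodes = motion$bnodes, nb = nb,
                 period_T = motion$period_T),
            class = "continuous_motion")
}

#' @rdname continuous_motion
#' @param cm a `continuous_motion`.
#' @param t time, s (wrapped periodically).
#' @return `n_boundary x 3` displacement matrix, m.
#' @export
interpolate_displacement <- function(cm, t) {
  stopifnot(inherits(cm, "continuous_motion"))
  matrix(eval_periodic_spline(cm$spline, t), cm$nb, 3L)
}

#' Interior extension of a boundary displacement
#'
#' `extension_operator` factorizes, once, the elliptic operator used to
#' extend boundary displacements into the volume: homogeneous isotropic
#' linear elasticity (default, with a configurable pseudo-Poisson ratio) or
#' a component-wise harmonic (Laplace) extension. Small cells can be
#' stiffened by the inverse of their reference volume so they deform the
#' least. `extend_displacement` then solves for the interior field; the trace
#' on the boundary equals the data (imposed by a large penalty, then
#' overwritten exactly).
#'
#' @param mesh a `tet_mesh`.
#' @param type `"elastic"` or `"harmonic"`.
#' @param poisson pseudo-Poisson ratio of the elastic extension.
#' @param stiffen exponent chi of the inverse-volume stiffening
#'   `(V_nominal / V_e)^chi`; 0 disables.
#' @param boundary_nodes vertex indices carrying Dirichlet data (defaults to
#'   all boundary vertices of the mesh).
#' @return an object of class `mesh_extension`.
#' @export
extension_operator <- function(mesh, type = c("elastic", "harmonic"),
                               poisson = 0.3, stiffen = 1,
                               boundary_nodes = NULL) {
  type <- match.arg(type)
  if (is.null(boundary_nodes)) {
    boundary_nodes <- sort(unique(as.vector(mesh$faces)))
  }
  n <- nrow(mesh$points)
  g <- tet_geom_cpp(mesh$points, mesh$tets)
  coef <- if (stiffen > 0) (mesh$h^3 / 6 / pmax(g$vol, 1e-300))^stiffen else
    rep(1, length(g$vol))
  pat <- sparse_pattern(mesh$tets, n)

  if (type == "harmonic") {
    K <- fill_sym(pat, stiffness_vals_cpp(g$vol, g$grads, coef))
    pen <- 1e8 * max(abs(Matrix::diag(K)))
    K <- K + Matrix::sparseMatrix(i = boundary_nodes, j = boundary_nodes,
                                  x = pen, dims = c(n, n), symmetric = TRUE)
    fac <- Matrix::Cholesky(K, LDL = FALSE)
    out <- list(type = type, n = n, pen = pen, fac = fac,
                boundary_nodes = boundary_nodes)
  } else {
    # plane-strain-like Lame parameters from E = 1
    lam <- poisson / ((1 + poisson) * (1 - 2 * poisson))
    mu <- 1 / (2 * (1 + poisson))
    blocks <- vector("list", 9L)
    for (a in 0:2) for (b in 0:2) {
      vals <- dirstiff_vals_cpp(g$vol, g$grads, coef, a, b)
      blocks[[3 * a + b + 1]] <- fill_gen(pat, vals)
    }
    B <- function(a, b) blocks[[3 * (a - 1) + (b - 1) + 1]]
    lap <- B(1, 1) + B(2, 2) + B(3, 3)
    rows <- vector("list", 3L)
    for (a in 1:3) {
      cols <- vector("list", 3L)
      for (b in 1:3) {
        # mu (grad u : grad v + grad u : grad v^T) + lam div u div v;
        # assembled up to a skew part that the symmetrization below removes
        blk <- (lam + mu) * B(b, a)
        if (a == b) blk <- blk + mu * lap
        cols[[b]] <- blk
      }
      rows[[a]] <- do.call(cbind, cols)
    }
    K <- do.call(rbind, rows)
    K <- methods::as(Matrix::forceSymmetric((K + Matrix::t(K)) / 2, "U"),
                     "CsparseMatrix")
    dirs <- c(boundary_nodes, boundary_nodes + n, boundary_nodes + 2L * n)
    pen <- 1e8 * max(abs(Matrix::diag(K)))
    K <- K + Matrix::sparseMatrix(i = dirs, j = dirs, x = pen,
                                  dims = c(3L * n, 3L * n), symmetric = TRUE)
    fac <- Matrix::Cholesky(K, LDL = FALSE)
    out <- list(type = type, n = n, pen = pen, fac = fac,
                boundary_nodes = boundary_nodes)
  }
  class(out) <- "mesh_extension"
  out
}

#' @rdname extension_operator
#' @param ext a `mesh_extension`.
#' @param boundary_disp displacement at `boundary_nodes`
#'   (`length(boundary_nodes) x 3`), m.
#' @return `n x 3` displacement over all vertices, m.
#' @export
extend_displacement <- function(ext, boundary_disp) {
  stopifnot(inherits(ext, "mesh_extension"),
            nrow(boundary_disp) == length(ext$boundary_nodes))
  n <- ext$n
  if (ext$type == "harmonic") {
    rhs <- matrix(0, n, 3)
    rhs[ext$boundary_nodes, ] <- ext$pen * boundary_disp
    d <- as.matrix(Matrix::solve(ext$fac, rhs, system = "A"))
  } else {
    rhs <- numeric(3 * n)
    for (c in 1:3) {
      rhs[ext$boundary_nodes + (c - 1L) * n] <- ext$pen * boundary_disp[, c]
    }
    sol <- as.numeric(Matrix::solve(ext$fac, rhs, system = "A"))
    d <- matrix(sol, n, 3)
  }
  d[ext$boundary_nodes, ] <- boundary_disp
  d
}

#' ALE mesh velocity by backward difference
#'
#' First-order backward difference of the extended displacement, consistent
#' with the solver's first-order time discretization.
#'
#' @param d_new,d_old displacement fields at the new and old time, m.
#' @param dt time step, s.
#' @return velocity field, m/s.
#' @export
mesh_velocity <- function(d_new, d_old, dt) {
  stopifnot(dt > 0)
  (d_new - d_old) / dt
}

## ---- shared sparse-pattern machinery ------------------------------------

# Fixed sparsity pattern of a P1 tet operator plus the index maps from the
# 16-entries-per-element stream into the x slots of the general (dgC) and
# symmetric-upper (dsC) templates.
#' @keywords internal
sparse_pattern <- function(tets, n) {
  M <- nrow(tets)
  # element stream order is row-major: entry 4*(a-1)+b is (row a, col b)
  ie <- matrix(0L, M, 16L); je <- matrix(0L, M, 16L)
  for (a in 1:4) for (b in 1:4) {
    ie[, 4 * (a - 1) + b] <- tets[, a]
    je[, 4 * (a - 1) + b] <- tets[, b]
  }
  iv <- as.vector(t(ie)); jv <- as.vector(t(je))
  G <- Matrix::sparseMatrix(i = iv, j = jv, x = 1, dims = c(n, n))
  G@x[] <- 0
  key <- function(i, j) (as.numeric(j) - 1) * n + i
  gi <- G@i + 1L
  gj <- rep.int(seq_len(n), diff(G@p))
  pos_gen <- match(key(iv, jv), key(gi, gj))
  S <- methods::as(Matrix::forceSymmetric(G, "U"), "CsparseMatrix")
  si <- S@i + 1L
  sj <- rep.int(seq_len(n), diff(S@p))
  upper <- iv <= jv
  pos_sym <- integer(length(iv))
  pos_sym[upper] <- match(key(iv[upper], jv[upper]), key(si, sj))
  pos_sym[!upper] <- 0L
  diag_gen <- match(key(seq_len(n), seq_len(n)), key(gi, gj))
  diag_sym <- match(key(seq_len(n), seq_len(n)), key(si, sj))
  list(n = n, G = G, S = S, pos_gen = pos_gen, pos_sym = pos_sym,
       diag_gen = diag_gen, diag_sym = diag_sym)
}

# build a general dgCMatrix from element values on the shared pattern
#' @keywords internal
fill_gen <- function(pat, vals, diag_add = NULL) {
  x <- fill_pattern_cpp(length(pat$G@x), pat$pos_gen, vals)
  if (!is.null(diag_add)) x[pat$diag_gen] <- x[pat$diag_gen] + diag_add
  A <- pat$G
  A@x <- as.numeric(x)
  A
}

# build a symmetric dsCMatrix (upper storage) from element values
#' @keywords internal
fill_sym <- function(pat, vals, diag_add = NULL) {
  x <- fill_pattern_cpp(length(pat$S@x), pat$pos_sym, vals)
  if (!is.null(diag_add)) x[pat$diag_sym] <- x[pat$diag_sym] + diag_add
  A <- pat$S
  A@x <- as.numeric(x)
  A
}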