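# Implicit-geometry tetrahedral mesher.
#
# Solids are described by approximate signed-distance functions (negative
# inside). A Cartesian grid over the bounding box is split into six
# tetrahedra per cube (Freudenthal subdivision); tetrahedra whose four
# vertices are inside the solid are kept and the resulting staircase boundary
# vertices are projected onto the zero level set along the finite-difference
# gradient. Tangled elements after projection are relaxed back toward their
# grid positions until all cell volumes are positive.

## ---- implicit primitives -------------------------------------------------

#' Implicit solid primitives and boolean operators
#'
#' Primitives are functions mapping an `n x 3` matrix of points to an
#' approximate signed distance (negative inside). They are used both to mesh
#' the idealized left-heart chambers and to label mesh regions.
#'
#' @param center numeric length-3 (or length-2 for `imp_cylinder_z`) center, m.
#' @param semiaxes numeric length-3 ellipsoid semi-axes, m.
#' @param r radius, m.
#' @param z1,z2 axial extent of a z-aligned cylinder, m.
#' @param zb plane offset for the half-space `z <= zb`.
#' @param ... primitives to combine.
#' @return a function `f(pts)` returning a numeric vector.
#' @examples
#' sph <- imp_sphere(c(0, 0, 0), 1)
#' sph(rbind(c(0, 0, 0), c(2, 0, 0))) # -1, 1
#' @export
imp_sphere <- function(center, r) {
  force(center); force(r)
  function(pts) sqrt(rowSums((pts - rep(center, each = nrow(pts)))^2)) - r
}

#' @rdname imp_sphere
#' @export
imp_ellipsoid <- function(center, semiaxes) {
  force(center); force(semiaxes)
  s <- min(semiaxes)
  function(pts) {
    q <- sweep(sweep(pts, 2, center, "-"), 2, semiaxes, "/")
    (sqrt(rowSums(q^2)) - 1) * s
  }
}

#' @rdname imp_sphere
#' @export
imp_halfspace_z <- function(zb) {
  force(zb)
  function(pts) pts[, 3] - zb
}

#' @rdname imp_sphere
#' @export
imp_cylinder_z <- function(center, r, z1, z2) {
  force(center); force(r); force(z1); force(z2)
  function(pts) {
    dr <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) - r
    dz <- pmax(z1 - pts[, 3], pts[, 3] - z2)
    inside <- pmin(pmax(dr, dz), 0)
    outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
    inside + outside
  }
}

#' @rdname imp_sphere
#' @param tilt tilt angle of the cylinder axis away from z in the x-z plane,
#'   radians; caps remain horizontal (z = `z1`, `z2`).
#' @export
imp_cylinder_tilted <- function(center, r, z1, z2, tilt = 0) {
  force(center); force(r); force(z1); force(z2); force(tilt)
  d <- c(sin(tilt), 0, cos(tilt))
  p0 <- c(center[1], center[2], z1)
  function(pts) {
    q <- sweep(pts, 2, p0, "-")
    s <- q %*% d
    dr <- sqrt(pmax(rowSums(q^2) - s^2, 0)) - r
    dz <- pmax(z1 - pts[, 3], pts[, 3] - z2)
    inside <- pmin(pmax(dr, dz), 0)
    outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
    drop(inside + outside)
  }
}

#' @rdname imp_sphere
#' @export
imp_union <- function(...) {
  fns <- list(...)
  function(pts) do.call(pmin, lapply(fns, function(f) f(pts)))
}

#' @rdname imp_sphere
#' @export
imp_intersect <- function(...) {
  fns <- list(...)
  function(pts) do.call(pmax, lapply(fns, function(f) f(pts)))
}

## ---- mesh construction ---------------------------------------------------

# Freudenthal subdivision: local cube corner indices (0..7 as bit xyz) for the
# six tetrahedra sharing the main diagonal 0-7, each positively oriented.
.freudenthal <- rbind(
  c(0L, 1L, 3L, 7L),
  c(0L, 3L, 2L, 7L),
  c(0L, 2L, 6L, 7L),
  c(0L, 6L, 4L, 7L),
  c(0L, 4L, 5L, 7L),
  c(0L, 5L, 1L, 7L)
)

#' Tetrahedral mesh of an implicit solid
#'
#' Meshes the region where `phi < 0` on a Cartesian grid of spacing `h`,
#' keeping fully interior tetrahedra and projecting boundary vertices onto the
#' zero level set (up to `newton` damped Newton steps along the
#' finite-difference gradient). Vertices whose projection would invert an
#' element are relaxed back toward their grid position.
#'
#' @param phi implicit function (negative inside), see [imp_sphere()].
#' @param bbox 2 x 3 matrix, rows = lower/upper corner of the bounding box (m).
#' @param h grid spacing, m.
#' @param project logical; project boundary vertices onto the surface.
#' @param newton maximum Newton projection steps.
#' @param snap_band grid vertices closer than `snap_band * h` to the surface
#'   are snapped onto it before extraction, which keeps the later boundary
#'   projection small and well conditioned.
#' @return a `tet_mesh` list with `points` (N x 3), `tets` (M x 4, 1-based,
#'   positively oriented), boundary `faces` (F x 3, outward-oriented), and the
#'   spacing `h`.
#' @export
voxel_tet_mesh <- function(phi, bbox, h, project = TRUE, newton = 5L,
                           snap_band = 0.45) {
  stopifnot(h > 0)
  xs <- seq(bbox[1, 1], bbox[2, 1], by = h)
  ys <- seq(bbox[1, 2], bbox[2, 2], by = h)
  zs <- seq(bbox[1, 3], bbox[2, 3], by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (nx < 2 || ny < 2 || nz < 2) stop("bounding box too small for spacing h")
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  vals <- phi(grid)
  if (project && snap_band > 0) {
    near <- which(abs(vals) < snap_band * h)
    if (length(near)) {
      grid[near, ] <- .newton_project(phi, grid[near, , drop = FALSE], h,
                                      steps = 3L, cap = 0.6 * h)
      vals[near] <- 0
    }
  }
  inside <- vals <= 0
  vid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)

  # cube lower corners
  cc <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L), k = seq_len(nz - 1L))
  corner_ids <- matrix(0L, nrow(cc), 8L)
  for (b in 0:7) {
    di <- bitwAnd(b, 1L); dj <- bitwAnd(bitwShiftR(b, 1L), 1L)
    dk <- bitwAnd(bitwShiftR(b, 2L), 1L)
    corner_ids[, b + 1L] <- vid(cc$i + di, cc$j + dj, cc$k + dk)
  }
  keep_cube <- rowSums(matrix(inside[corner_ids], nrow(cc), 8L)) == 8L
  # only fully interior cubes can contribute fully interior tets quickly;
  # partially inside cubes may still contain interior tets, so check per tet
  partial <- rowSums(matrix(inside[corner_ids], nrow(cc), 8L)) > 0L & !keep_cube
  tet_list <- vector("list", 6L)
  use <- keep_cube | partial
  cid <- corner_ids[use, , drop = FALSE]
  for (t in 1:6) {
    tet_list[[t]] <- cid[, .freudenthal[t, ] + 1L, drop = FALSE]
  }
  tets <- do.call(rbind, tet_list)
  all_in <- matrix(inside[tets], nrow(tets), 4L)
  tets <- tets[rowSums(all_in) == 4L, , drop = FALSE]
  if (nrow(tets) == 0L) stop("no interior tetrahedra; refine h or enlarge bbox")

  # compact vertex numbering
  used <- sort(unique(as.vector(tets)))
  remap <- integer(length(vals)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], nrow(tets), 4L)
  pts <- grid[used, , drop = FALSE]

  # fix orientation (Freudenthal table is consistent, but verify cheaply)
  g <- tet_geom_cpp(pts, tets)
  neg <- g$vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  # drop slivers flattened onto the surface by grid snapping
  vol <- abs(g$vol)
  keep <- vol > 5e-3 * h^3 / 6
  tets <- tets[keep, , drop = FALSE]
  used2 <- sort(unique(as.vector(tets)))
  remap2 <- integer(nrow(pts)); remap2[used2] <- seq_along(used2)
  tets <- matrix(remap2[tets], nrow(tets), 4L)
  pts <- pts[used2, , drop = FALSE]

  faces <- boundary_faces(tets)
  mesh <- list(points = pts, tets = tets, faces = faces, h = h)
  class(mesh) <- "tet_mesh"

  if (project) {
    mesh <- .project_boundary(mesh, phi, h, newton)
    mesh <- .drop_slivers(mesh, qmin = 0.02)
    mesh <- .drop_folded(mesh)
  }
  mesh
}

# Detect folded cell pairs: two tetrahedra sharing a face while lying on the
# SAME side of it (both stored orientations have equal parity). Such pairs
# overlap in space even though both volumes are positive, and they break the
# divergence-theorem bookkeeping of region volumes.
#' @keywords internal
.folded_cells <- function(tets) {
  m <- nrow(tets)
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
  owner <- rep(seq_len(m), 4L)
  a <- f[, 1]; b <- f[, 2]; cc <- f[, 3]
  s1 <- pmin(a, b, cc); s3 <- pmax(a, b, cc)
  s2 <- as.numeric(a) + b + cc - s1 - s3
  nv <- max(f) + 1
  key <- (s1 * nv + s2) * nv + s3
  even <- (a == s1 & b == s2) | (a == s2 & b == s3) | (a == s3 & b == s1)
  o <- order(key)
  k <- key[o]
  same <- which(k[-length(k)] == k[-1])
  bad <- same[even[o][same] == even[o][same + 1L]]
  unique(c(owner[o][bad], owner[o][bad + 1L]))
}

# iteratively remove folded cells (smaller member of each overlapping pair)
#' @keywords internal
.drop_folded <- function(mesh, passes = 6L) {
  for (p in seq_len(passes)) {
    bad <- .folded_cells(mesh$tets)
    if (length(bad) == 0L) return(mesh)
    vol <- tet_geom_cpp(mesh$points, mesh$tets)$vol
    # drop the smaller cells among the offenders
    thr <- stats::median(vol[bad])
    drop <- bad[vol[bad] <= thr]
    keep <- rep(TRUE, nrow(mesh$tets)); keep[drop] <- FALSE
    mesh <- .drop_cells(mesh, keep)
  }
  mesh
}

# remove near-degenerate cells (flat caps lying on the projected surface);
# the boundary recedes by a negligible volume and regains quality
.drop_slivers <- function(mesh, qmin) {
  nominal <- mesh$h^3 / 6
  vol <- tet_geom_cpp(mesh$points, mesh$tets)$vol
  .drop_cells(mesh, vol > qmin * nominal)
}

# keep the flagged cells, compact vertex numbering, rebuild the boundary
#' @keywords internal
.drop_cells <- function(mesh, keep) {
  if (all(keep)) return(mesh)
  tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(mesh$points)); remap[used] <- seq_along(used)
  mesh$tets <- matrix(remap[tets], nrow(tets), 4L)
  mesh$points <- mesh$points[used, , drop = FALSE]
  mesh$faces <- boundary_faces(mesh$tets)
  mesh$boundary_vertices <- sort(unique(as.vector(mesh$faces)))
  mesh
}

# outward-oriented boundary faces of a positively oriented tet mesh
#' @keywords internal
boundary_faces <- function(tets) {
  f <- rbind(
    tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
    tets[, c(1, 4, 3)], tets[, c(2, 3, 4)]
  )
  s1 <- pmin(f[, 1], f[, 2], f[, 3])
  s3 <- pmax(f[, 1], f[, 2], f[, 3])
  s2 <- as.numeric(f[, 1]) + f[, 2] + f[, 3] - s1 - s3
  nv <- max(f) + 1
  key <- (s1 * nv + s2) * nv + s3
  f[!(duplicated(key) | duplicated(key, fromLast = TRUE)), , drop = FALSE]
}

# damped Newton projection of points onto the zero level set
.newton_project <- function(phi, p, h, steps = 5L, cap = NULL) {
  if (is.null(cap)) cap <- h
  eps <- 1e-4 * h
  for (it in seq_len(steps)) {
    f <- phi(p)
    if (all(abs(f) < 1e-6 * h)) break
    gx <- (phi(p + matrix(c(eps, 0, 0), nrow(p), 3, byrow = TRUE)) - f) / eps
    gy <- (phi(p + matrix(c(0, eps, 0), nrow(p), 3, byrow = TRUE)) - f) / eps
    gz <- (phi(p + matrix(c(0, 0, eps), nrow(p), 3, byrow = TRUE)) - f) / eps
    g2 <- pmax(gx^2 + gy^2 + gz^2, 1e-12)
    step <- cbind(f * gx / g2, f * gy / g2, f * gz / g2)
    len <- sqrt(rowSums(step^2))
    scl <- pmin(1, cap / pmax(len, 1e-30))
    p <- p - step * scl
  }
  p
}

.project_boundary <- function(mesh, phi, h, newton) {
  bverts <- sort(unique(as.vector(mesh$faces)))
  p0 <- mesh$points[bverts, , drop = FALSE]
  p <- .newton_project(phi, p0, h, steps = newton)
  pts <- mesh$points
  pts[bverts, ] <- p
  # untangle: relax offending boundary vertices back toward grid positions
  for (pass in 1:12) {
    vol <- tet_geom_cpp(pts, mesh$tets)$vol
    bad <- vol <= 1e-6 * h^3 / 6
    if (!any(bad)) break
    badv <- unique(as.vector(mesh$tets[bad, , drop = FALSE]))
    hit <- match(badv, bverts)
    hit <- hit[!is.na(hit)]
    pts[bverts[hit], ] <- 0.5 * (pts[bverts[hit], , drop = FALSE] +
                                   p0[hit, , drop = FALSE])
    p0[hit, ] <- pts[bverts[hit], ] # converge toward a valid configuration
  }
  vol <- tet_geom_cpp(pts, mesh$tets)$vol
  if (any(vol <= 0)) stop("boundary projection produced inverted elements")
  mesh$points <- pts
  mesh$boundary_vertices <- bverts
  mesh
}

#' Laplacian mesh smoothing with surface re-projection
#'
#' Smooths interior vertices over all neighbours and boundary vertices over
#' boundary neighbours (re-projected onto the implicit surface), guarded so
#' no cell volume becomes non-positive. Lifts the worst-cell quality left by
#' the staircase projection.
#'
#' @param mesh a `tet_mesh` from [voxel_tet_mesh()].
#' @param phi the implicit function the mesh was built from.
#' @param h grid spacing, m.
#' @param passes smoothing sweeps.
#' @param fixed optional vertex indices that must not move (e.g. regions
#'   whose vertices must stay on grid planes for flux sections).
#' @param drop_qmin cells below this fraction of the nominal cell volume are
#'   removed after smoothing (0 disables).
#' @return the smoothed `tet_mesh`.
#' @export
smooth_tet_mesh <- function(mesh, phi, h, passes = 3L, fixed = NULL,
                            drop_qmin = 0.02) {
  tets <- mesh$tets
  n <- nrow(mesh$points)
  edges <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  edges <- rbind(edges, edges[, c(2, 1)])
  bv <- mesh$boundary_vertices
  is_b <- logical(n); is_b[bv] <- TRUE
  # boundary vertices average only over boundary neighbours (surface-tangent
  # smoothing), interior vertices over all neighbours
  keep <- !is_b[edges[, 1]] | is_b[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  deg <- tabulate(edges[, 1], n)
  pts <- mesh$points
  idx <- sort(unique(edges[, 1]))
  for (pass in seq_len(passes)) {
    acc <- matrix(0, n, 3)
    acc[idx, ] <- rowsum(pts[edges[, 2], , drop = FALSE], edges[, 1],
                         reorder = TRUE)
    avg <- acc / pmax(deg, 1L)
    new_pts <- 0.5 * pts + 0.5 * avg
    new_pts[deg == 0L, ] <- pts[deg == 0L, ]
    new_pts[bv, ] <- .newton_project(phi, new_pts[bv, , drop = FALSE], h,
                                     steps = 3L, cap = 0.5 * h)
    if (!is.null(fixed)) new_pts[fixed, ] <- pts[fixed, ]
    rx <- relax_to_valid(new_pts, pts, tets)
    if (!rx$ok) break
    pts <- rx$points
  }
  mesh$points <- pts
  if (drop_qmin > 0) mesh <- .drop_slivers(mesh, qmin = drop_qmin)
  .drop_folded(mesh)
}

## ---- mesh utilities ------------------------------------------------------

#' Mesh measures
#'
#' `mesh_cell_volumes` returns per-tetrahedron volumes; `mesh_volume` the total
#' enclosed volume; `face_geometry` areas, outward unit normals and centroids
#' of a set of (oriented) triangular faces; `surface_enclosed_volume` the
#' divergence-theorem volume of a closed oriented surface.
#'
#' @param mesh a `tet_mesh`, or for the face helpers a points matrix.
#' @param points N x 3 vertex coordinates.
#' @param faces F x 3 oriented triangles (1-based).
#' @return numeric vector / scalar / list as documented above.
#' @export
mesh_cell_volumes <- function(mesh) {
  tet_geom_cpp(mesh$points, mesh$tets)$vol
}

#' @rdname mesh_cell_volumes
#' @export
mesh_volume <- function(mesh) sum(mesh_cell_volumes(mesh))

#' @rdname mesh_cell_volumes
#' @export
face_geometry <- function(points, faces) {
  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE]
  c <- points[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(cr^2))
  list(
    area = nrm / 2,
    normal = cr / pmax(nrm, 1e-300),
    centroid = (a + b + c) / 3
  )
}

#' @rdname mesh_cell_volumes
#' @export
surface_enclosed_volume <- function(points, faces) {
  fg <- face_geometry(points, faces)
  sum(fg$area * rowSums(fg$centroid * fg$normal)) / 3
}

# Vertex adjacency (as an edge list plus degrees) for repair/smoothing.
#' @keywords internal
vertex_adjacency <- function(tets, n) {
  e <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
             tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  list(edges = e, deg = tabulate(e[, 1], n), n = n,
       idx = sort(unique(e[, 1])))
}

# Localized mesh repair: vertices of non-positive cells are blended toward
# the average of their neighbours, which follows the surrounding motion.
#' @keywords internal
repair_tet_mesh <- function(pts, tets, adj, passes = 12L, min_vol = 0) {
  moved <- 0L
  for (pass in seq_len(passes)) {
    vol <- tet_geom_cpp(pts, tets)$vol
    bad <- vol <= min_vol
    if (!any(bad)) return(list(points = pts, moved = moved, ok = TRUE))
    v <- unique(as.vector(tets[bad, , drop = FALSE]))
    acc <- rowsum(pts[adj$edges[, 2], , drop = FALSE], adj$edges[, 1],
                  reorder = TRUE)
    avg <- matrix(0, adj$n, 3)
    avg[adj$idx, ] <- acc
    avg <- avg / pmax(adj$deg, 1L)
    pts[v, ] <- 0.5 * pts[v, , drop = FALSE] + 0.5 * avg[v, , drop = FALSE]
    moved <- moved + length(v)
  }
  vol <- tet_geom_cpp(pts, tets)$vol
  list(points = pts, moved = moved, ok = all(vol > min_vol))
}

# Blend vertices of non-positive cells back toward a known-valid
# configuration until all cell volumes are positive. `only` optionally
# restricts which vertices may move (e.g. interior ones).
#' @keywords internal
relax_to_valid <- function(pts_new, pts_safe, tets, passes = 30L,
                           min_vol = 0, only = NULL) {
  moved <- 0L
  for (pass in seq_len(passes)) {
    vol <- tet_geom_cpp(pts_new, tets)$vol
    bad <- vol <= min_vol
    if (!any(bad)) return(list(points = pts_new, relaxed = moved, ok = TRUE))
    v <- unique(as.vector(tets[bad, , drop = FALSE]))
    if (!is.null(only)) v <- intersect(v, only)
    if (length(v) == 0L) break
    pts_new[v, ] <- 0.5 * (pts_new[v, , drop = FALSE] +
                             pts_safe[v, , drop = FALSE])
    moved <- moved + length(v)
  }
  vol <- tet_geom_cpp(pts_new, tets)$vol
  list(points = pts_new, relaxed = moved, ok = all(vol > min_vol))
}

#' @keywords internal
tet_centroids <- function(mesh) {
  (mesh$points[mesh$tets[, 1], ] + mesh$points[mesh$tets[, 2], ] +
     mesh$points[mesh$tets[, 3], ] + mesh$points[mesh$tets[, 4], ]) / 4
}
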