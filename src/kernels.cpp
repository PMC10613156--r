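// Low-level kernels for P1 tetrahedral finite elements and geometric queries.
// All element-loop hot paths of the flow solver live here; sparse linear
// algebra stays on the R side (Matrix package).
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// Per-tet signed volumes and P1 basis gradients.
// points: N x 3, tets: M x 4 (1-based). Returns list(vol = M, grads = M x 12)
// with grads row layout g1x g1y g1z g2x ... g4z.
// [[Rcpp::export]]
List tet_geom_cpp(const arma::mat& points, const arma::imat& tets) {
  const arma::uword M = tets.n_rows;
  arma::vec vol(M);
  arma::mat grads(M, 12);
  arma::mat33 A, Ai;
  for (arma::uword e = 0; e < M; ++e) {
    arma::uword i1 = tets(e, 0) - 1, i2 = tets(e, 1) - 1,
                i3 = tets(e, 2) - 1, i4 = tets(e, 3) - 1;
    arma::rowvec3 p1 = points.row(i1);
    A.col(0) = (points.row(i2) - p1).t();
    A.col(1) = (points.row(i3) - p1).t();
    A.col(2) = (points.row(i4) - p1).t();
    double det = arma::det(A);
    vol(e) = det / 6.0;
    if (std::abs(det) < 1e-300) {
      grads.row(e).zeros();
      continue;
    }
    Ai = arma::inv(A);
    // rows of Ai are gradients of barycentric coords 2..4
    double g1x = 0, g1y = 0, g1z = 0;
    for (int k = 0; k < 3; ++k) {
      grads(e, 3 * (k + 1) + 0) = Ai(k, 0);
      grads(e, 3 * (k + 1) + 1) = Ai(k, 1);
      grads(e, 3 * (k + 1) + 2) = Ai(k, 2);
      g1x -= Ai(k, 0); g1y -= Ai(k, 1); g1z -= Ai(k, 2);
    }
    grads(e, 0) = g1x; grads(e, 1) = g1y; grads(e, 2) = g1z;
  }
  return List::create(_["vol"] = vol, _["grads"] = grads);
}

// Lumped mass vector: ML_i = sum_e V_e/4 over elements containing node i.
// [[Rcpp::export]]
NumericVector lumped_mass_cpp(const arma::imat& tets, const arma::vec& vol,
                              int n_nodes) {
  NumericVector ml(n_nodes);
  for (arma::uword e = 0; e < tets.n_rows; ++e) {
    double w = vol(e) / 4.0;
    for (int a = 0; a < 4; ++a) ml[tets(e, a) - 1] += w;
  }
  return ml;
}

// Element stiffness values coef_e * V_e * (g_i . g_j), emitted in the fixed
// 16-entries-per-element order used to build the sparsity pattern.
// [[Rcpp::export]]
NumericVector stiffness_vals_cpp(const arma::vec& vol, const arma::mat& grads,
                                 const arma::vec& coef) {
  const arma::uword M = vol.n_elem;
  NumericVector out(16 * M);
  for (arma::uword e = 0; e < M; ++e) {
    double cv = coef(e) * vol(e);
    const double* g = grads.colptr(0); // column-major; use explicit access
    double ge[12];
    for (int k = 0; k < 12; ++k) ge[k] = grads(e, k);
    arma::uword base = 16 * e;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double dot = ge[3 * a] * ge[3 * b] + ge[3 * a + 1] * ge[3 * b + 1] +
                     ge[3 * a + 2] * ge[3 * b + 2];
        out[base + 4 * a + b] = cv * dot;
      }
    (void)g;
  }
  return out;
}

// Directional stiffness values coef_e * V_e * g_i[a] * g_j[b] (a, b in 0..2),
// for assembling anisotropic/elastic operators on the shared pattern.
// [[Rcpp::export]]
NumericVector dirstiff_vals_cpp(const arma::vec& vol, const arma::mat& grads,
                                const arma::vec& coef, int a, int b) {
  const arma::uword M = vol.n_elem;
  NumericVector out(16 * M);
  for (arma::uword e = 0; e < M; ++e) {
    double cv = coef(e) * vol(e);
    arma::uword base = 16 * e;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        out[base + 4 * i + j] = cv * grads(e, 3 * i + a) * grads(e, 3 * j + b);
  }
  return out;
}

// Fused assembly: the three weak-divergence operators' x slots in one pass
// (columns = spatial components), avoiding intermediate value streams.
// [[Rcpp::export]]
NumericMatrix gdiv_fill3_cpp(const arma::vec& vol, const arma::mat& grads,
                             const IntegerVector& pos, int nnz) {
  const arma::uword M = vol.n_elem;
  NumericMatrix X(nnz, 3);
  double* x0 = &X(0, 0); double* x1 = &X(0, 1); double* x2 = &X(0, 2);
  for (arma::uword e = 0; e < M; ++e) {
    double v4 = vol(e) / 4.0;
    arma::uword base = 16 * e;
    for (int b = 0; b < 4; ++b) {
      double gx = v4 * grads(e, 3 * b + 0);
      double gy = v4 * grads(e, 3 * b + 1);
      double gz = v4 * grads(e, 3 * b + 2);
      for (int a = 0; a < 4; ++a) {
        int p = pos[base + 4 * a + b];
        if (p > 0) { x0[p - 1] += gx; x1[p - 1] += gy; x2[p - 1] += gz; }
      }
    }
  }
  return X;
}

// Fused symmetric stiffness assembly straight into the x slot.
// [[Rcpp::export]]
NumericVector stiff_fill_cpp(const arma::vec& vol, const arma::mat& grads,
                             const arma::vec& coef, const IntegerVector& pos,
                             int nnz) {
  const arma::uword M = vol.n_elem;
  NumericVector x(nnz);
  for (arma::uword e = 0; e < M; ++e) {
    double cv = coef(e) * vol(e);
    double ge[12];
    for (int k = 0; k < 12; ++k) ge[k] = grads(e, k);
    arma::uword base = 16 * e;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        int p = pos[base + 4 * a + b];
        if (p > 0) {
          x[p - 1] += cv * (ge[3 * a] * ge[3 * b] +
                            ge[3 * a + 1] * ge[3 * b + 1] +
                            ge[3 * a + 2] * ge[3 * b + 2]);
        }
      }
  }
  return x;
}

// Scatter-accumulate element-entry values into the x slot of a fixed sparse
// pattern. pos is 1-based position per entry (0 = dropped, e.g. strict lower
// triangle of a symmetric matrix).
// [[Rcpp::export]]
NumericVector fill_pattern_cpp(int nnz, const IntegerVector& pos,
                               const NumericVector& vals) {
  NumericVector x(nnz);
  const int n = pos.size();
  for (int k = 0; k < n; ++k) {
    int p = pos[k];
    if (p > 0) x[p - 1] += vals[k];
  }
  return x;
}

// Explicit convection term: nodal vector r_i = sum_e (V_e/4) (w_c . grad u)_e
// with w_c the element-average advecting velocity. u, w are N x 3.
// [[Rcpp::export]]
NumericMatrix convection_term_cpp(const arma::imat& tets, const arma::vec& vol,
                                  const arma::mat& grads, const arma::mat& u,
                                  const arma::mat& w) {
  const arma::uword M = tets.n_rows, N = u.n_rows;
  NumericMatrix out(N, 3);
  for (arma::uword e = 0; e < M; ++e) {
    arma::uword id[4];
    for (int a = 0; a < 4; ++a) id[a] = tets(e, a) - 1;
    double wc[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) wc[c] += 0.25 * w(id[a], c);
    // Gu[a][b] = d u_a / d x_b
    double Gu[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < 4; ++j)
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) Gu[a][b] += u(id[j], a) * grads(e, 3 * j + b);
    double conv[3];
    for (int a = 0; a < 3; ++a)
      conv[a] = Gu[a][0] * wc[0] + Gu[a][1] * wc[1] + Gu[a][2] * wc[2];
    double wv = vol(e) / 4.0;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) out(id[a], c) += wv * conv[c];
  }
  return out;
}

// Weak nodal gradient of a scalar field: r_i = sum_e (V_e/4) (grad f)_e.
// Divide by the lumped mass on the R side to recover a nodal gradient.
// [[Rcpp::export]]
NumericMatrix scalar_grad_scatter_cpp(const arma::imat& tets,
                                      const arma::vec& vol,
                                      const arma::mat& grads,
                                      const arma::vec& f) {
  const arma::uword M = tets.n_rows;
  NumericMatrix out(f.n_elem, 3);
  for (arma::uword e = 0; e < M; ++e) {
    arma::uword id[4];
    double gf[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a) {
      id[a] = tets(e, a) - 1;
      for (int c = 0; c < 3; ++c) gf[c] += f(id[a]) * grads(e, 3 * a + c);
    }
    double wv = vol(e) / 4.0;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) out(id[a], c) += wv * gf[c];
  }
  return out;
}

// Weak-divergence operator values: entry (a, b) of each element block is
// V_e/4 * g_b[c] (row-independent), so that G_c u_c accumulates the nodal
// weak divergence and crossprod(G_c, p) the adjoint pressure gradient.
// [[Rcpp::export]]
NumericVector gdiv_vals_cpp(const arma::vec& vol, const arma::mat& grads,
                            int c) {
  const arma::uword M = vol.n_elem;
  NumericVector out(16 * M);
  for (arma::uword e = 0; e < M; ++e) {
    double v4 = vol(e) / 4.0;
    arma::uword base = 16 * e;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        out[base + 4 * a + b] = v4 * grads(e, 3 * b + c);
  }
  return out;
}

// Integrated-by-parts pressure term: r_{i,c} = sum_e V_e * mean(p)_e * g_i[c]
// (the volume part of (p, div v)).
// [[Rcpp::export]]
NumericMatrix pdivv_scatter_cpp(const arma::imat& tets, const arma::vec& vol,
                                const arma::mat& grads, const arma::vec& p) {
  const arma::uword M = tets.n_rows;
  NumericMatrix out(p.n_elem, 3);
  for (arma::uword e = 0; e < M; ++e) {
    arma::uword id[4];
    double pbar = 0;
    for (int a = 0; a < 4; ++a) {
      id[a] = tets(e, a) - 1;
      pbar += 0.25 * p(id[a]);
    }
    double w = vol(e) * pbar;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) out(id[a], c) += w * grads(e, 3 * a + c);
  }
  return out;
}

// Element-wise velocity gradient tensors, M x 9, row layout
// (du1/dx1, du1/dx2, du1/dx3, du2/dx1, ..., du3/dx3).
// [[Rcpp::export]]
NumericMatrix elem_velocity_grad_cpp(const arma::imat& tets,
                                     const arma::mat& grads,
                                     const arma::mat& u) {
  const arma::uword M = tets.n_rows;
  NumericMatrix out(M, 9);
  for (arma::uword e = 0; e < M; ++e) {
    double Gu[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < 4; ++j) {
      arma::uword id = tets(e, j) - 1;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) Gu[a][b] += u(id, a) * grads(e, 3 * j + b);
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) out(e, 3 * a + b) = Gu[a][b];
  }
  return out;
}

// Element-wise divergence of a vector field.
// [[Rcpp::export]]
NumericVector elem_divergence_cpp(const arma::imat& tets, const arma::mat& grads,
                                  const arma::mat& u) {
  const arma::uword M = tets.n_rows;
  NumericVector out(M);
  for (arma::uword e = 0; e < M; ++e) {
    double d = 0;
    for (int j = 0; j < 4; ++j) {
      arma::uword id = tets(e, j) - 1;
      for (int a = 0; a < 3; ++a) d += u(id, a) * grads(e, 3 * j + a);
    }
    out[e] = d;
  }
  return out;
}

// sigma-model differential operator D_sigma per element from the 3x3 velocity
// gradient: with singular values s1 >= s2 >= s3 >= 0,
// D = s3 (s1 - s2)(s2 - s3) / s1^2, defined as 0 when s1 == 0.
// [[Rcpp::export]]
NumericVector sigma_dsigma_cpp(const NumericMatrix& gradmat) {
  const int M = gradmat.nrow();
  NumericVector out(M);
  for (int e = 0; e < M; ++e) {
    double G[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        G[a][b] = gradmat(e, 3 * a + b);
        if (!std::isfinite(G[a][b])) stop("non-finite velocity gradient entries");
      }
    // B = G^T G is symmetric PSD; singular values are sqrt(eig(B)).
    // Closed-form symmetric 3x3 eigenvalues (trigonometric formula).
    double B[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int a = 0; a < 3; ++a)
      for (int b = a; b < 3; ++b) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += G[k][a] * G[k][b];
        B[a][b] = s; B[b][a] = s;
      }
    double q = (B[0][0] + B[1][1] + B[2][2]) / 3.0;
    double p2 = (B[0][0] - q) * (B[0][0] - q) + (B[1][1] - q) * (B[1][1] - q) +
                (B[2][2] - q) * (B[2][2] - q) +
                2.0 * (B[0][1] * B[0][1] + B[0][2] * B[0][2] +
                       B[1][2] * B[1][2]);
    if (p2 <= 0.0) { out[e] = 0.0; continue; } // isotropic: s1 = s2 = s3
    double p = std::sqrt(p2 / 6.0);
    double b00 = B[0][0] - q, b11 = B[1][1] - q, b22 = B[2][2] - q;
    double detBq =
        b00 * (b11 * b22 - B[1][2] * B[1][2]) -
        B[0][1] * (B[0][1] * b22 - B[1][2] * B[0][2]) +
        B[0][2] * (B[0][1] * B[1][2] - b11 * B[0][2]);
    double r = detBq / (2.0 * p * p * p);
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0943951023931953); // +2pi/3
    double e2 = 3.0 * q - e1 - e3;
    double s1 = std::sqrt(std::max(e1, 0.0));
    double s2 = std::sqrt(std::max(e2, 0.0));
    double s3 = std::sqrt(std::max(e3, 0.0));
    // guard the ordering against round-off so D_sigma stays >= 0
    if (s2 > s1) std::swap(s1, s2);
    if (s3 > s2) { std::swap(s2, s3); if (s2 > s1) std::swap(s1, s2); }
    out[e] = (s1 <= 0.0) ? 0.0 : s3 * (s1 - s2) * (s2 - s3) / (s1 * s1);
  }
  return out;
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Squared distance from point p to triangle (a, b, c); Ericson, RTCD ch. 5.
static double pt_tri_dist2(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot3(ap, ap);
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3), q[3];
    for (int k = 0; k < 3; ++k) q[k] = ap[k] - v * ab[k];
    return dot3(q, q);
  }
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6), q[3];
    for (int k = 0; k < 3; ++k) q[k] = ap[k] - w * ac[k];
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6)), q[3];
    for (int k = 0; k < 3; ++k) q[k] = bp[k] - w * (c[k] - b[k]);
    return dot3(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom, q[3];
  for (int k = 0; k < 3; ++k) q[k] = ap[k] - v * ab[k] - w * ac[k];
  return dot3(q, q);
}

// Minimum unsigned distance from each query point to a triangle soup.
// tri: T x 9 rows (ax ay az bx by bz cx cy cz).
// [[Rcpp::export]]
NumericVector tri_min_dist_cpp(const NumericMatrix& pts,
                               const NumericMatrix& tri) {
  const int P = pts.nrow(), T = tri.nrow();
  NumericVector out(P);
  for (int i = 0; i < P; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int t = 0; t < T; ++t) {
      double a[3] = {tri(t, 0), tri(t, 1), tri(t, 2)};
      double b[3] = {tri(t, 3), tri(t, 4), tri(t, 5)};
      double c[3] = {tri(t, 6), tri(t, 7), tri(t, 8)};
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Brute-force point location in a tet mesh. Returns the 1-based element index
// maximizing the minimum barycentric coordinate (0 if the mesh is empty) and
// the barycentric coordinates there.
// [[Rcpp::export]]
List locate_points_cpp(const arma::mat& query, const arma::mat& points,
                       const arma::imat& tets) {
  const arma::uword Q = query.n_rows, M = tets.n_rows;
  IntegerVector elem(Q);
  NumericMatrix bary(Q, 4);
  arma::mat33 A;
  std::vector<arma::mat33> Ai(M);
  std::vector<arma::vec3> P1(M);
  std::vector<bool> ok(M);
  for (arma::uword e = 0; e < M; ++e) {
    arma::rowvec3 p1 = points.row(tets(e, 0) - 1);
    A.col(0) = (points.row(tets(e, 1) - 1) - p1).t();
    A.col(1) = (points.row(tets(e, 2) - 1) - p1).t();
    A.col(2) = (points.row(tets(e, 3) - 1) - p1).t();
    ok[e] = std::abs(arma::det(A)) > 1e-300;
    if (ok[e]) Ai[e] = arma::inv(A);
    P1[e] = p1.t();
  }
  for (arma::uword q = 0; q < Q; ++q) {
    double bestmin = -1e300;
    arma::uword beste = 0;
    arma::vec3 bestl;
    bestl.zeros();
    for (arma::uword e = 0; e < M; ++e) {
      if (!ok[e]) continue;
      arma::vec3 l = Ai[e] * (query.row(q).t() - P1[e]);
      double l0 = 1.0 - l(0) - l(1) - l(2);
      double mn = std::min(std::min(l0, l(0)), std::min(l(1), l(2)));
      if (mn > bestmin) {
        bestmin = mn; beste = e; bestl = l;
        if (mn >= -1e-12) break; // strictly inside, stop scanning
      }
    }
    elem[q] = beste + 1;
    bary(q, 0) = 1.0 - bestl(0) - bestl(1) - bestl(2);
    bary(q, 1) = bestl(0); bary(q, 2) = bestl(1); bary(q, 3) = bestl(2);
  }
  return List::create(_["elem"] = elem, _["bary"] = bary);
}
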