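// Low-level kernels for quadratic (10-node) tetrahedral finite elements.
//
// Local node ordering follows the VTK quadratic tetrahedron: corners 1-4,
// then mid-edge nodes on edges (1,2),(2,3),(1,3),(1,4),(2,4),(3,4).
// Mid-edge nodes are assumed to sit at straight-edge midpoints, so the
// geometric mapping is affine and the Jacobian is constant per element.
// Voigt order: (xx, yy, zz, xy, yz, xz) with engineering shear strains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GA = 0.5854101966249685;
static const double GB = 0.1381966011250105;

// 4-point rule, barycentric coordinates (L1, L2, L3, L4), weight 1/4 each
// (reference volume 1/6 folded into detJ factor below).
static void gauss_bary(int g, double L[4]) {
  for (int i = 0; i < 4; ++i) L[i] = GB;
  L[g] = GA;
}

// shape functions at barycentric L
static void shape_N(const double L[4], double N[10]) {
  N[0] = L[0] * (2 * L[0] - 1);
  N[1] = L[1] * (2 * L[1] - 1);
  N[2] = L[2] * (2 * L[2] - 1);
  N[3] = L[3] * (2 * L[3] - 1);
  N[4] = 4 * L[0] * L[1];
  N[5] = 4 * L[1] * L[2];
  N[6] = 4 * L[0] * L[2];
  N[7] = 4 * L[0] * L[3];
  N[8] = 4 * L[1] * L[3];
  N[9] = 4 * L[2] * L[3];
}

// derivatives wrt natural coords (xi, eta, zeta) = (L2, L3, L4)
static void shape_dN(const double L[4], arma::mat::fixed<10, 3>& dN) {
  const double d1 = 4 * L[0] - 1; // dN1/dL1
  // corner nodes
  dN(0, 0) = -d1; dN(0, 1) = -d1; dN(0, 2) = -d1;
  dN(1, 0) = 4 * L[1] - 1; dN(1, 1) = 0; dN(1, 2) = 0;
  dN(2, 0) = 0; dN(2, 1) = 4 * L[2] - 1; dN(2, 2) = 0;
  dN(3, 0) = 0; dN(3, 1) = 0; dN(3, 2) = 4 * L[3] - 1;
  // edge nodes: N5 = 4 L1 L2, etc.  dL1/dxi = -1 for all natural coords
  dN(4, 0) = 4 * (L[0] - L[1]); dN(4, 1) = -4 * L[1]; dN(4, 2) = -4 * L[1];
  dN(5, 0) = 4 * L[2]; dN(5, 1) = 4 * L[1]; dN(5, 2) = 0;
  dN(6, 0) = -4 * L[2]; dN(6, 1) = 4 * (L[0] - L[2]); dN(6, 2) = -4 * L[2];
  dN(7, 0) = -4 * L[3]; dN(7, 1) = -4 * L[3]; dN(7, 2) = 4 * (L[0] - L[3]);
  dN(8, 0) = 4 * L[3]; dN(8, 1) = 0; dN(8, 2) = 4 * L[1];
  dN(9, 0) = 0; dN(9, 1) = 4 * L[3]; dN(9, 2) = 4 * L[2];
}

static void material_D(double E, double nu, arma::mat::fixed<6, 6>& D) {
  D.zeros();
  const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = E / (2 * (1 + nu));
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) D(i, j) = (i == j) ? lam + 2 * mu : lam;
  D(3, 3) = D(4, 4) = D(5, 5) = mu;
}

static void material_Cinv(double E, double nu, arma::mat::fixed<6, 6>& S) {
  S.zeros();
  const double mu = E / (2 * (1 + nu));
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) S(i, j) = (i == j) ? 1.0 / E : -nu / E;
  S(3, 3) = S(4, 4) = S(5, 5) = 1.0 / mu;
}

// constant Jacobian from corner nodes; returns detJ, fills Jinv
static double corner_jacobian(const arma::mat& nodes, const IntegerMatrix& elems,
                              int e, arma::mat::fixed<3, 3>& Jinv) {
  arma::mat::fixed<3, 3> J;
  const int n1 = elems(e, 0) - 1;
  for (int c = 0; c < 3; ++c) {
    for (int d = 0; d < 3; ++d)
      J(d, c) = nodes(elems(e, c + 1) - 1, d) - nodes(n1, d);
  }
  const double detJ = arma::det(J);
  Jinv = arma::inv(J);
  return detJ;
}

static void fill_B(const arma::mat::fixed<10, 3>& G, arma::mat::fixed<6, 30>& B) {
  B.zeros();
  for (int i = 0; i < 10; ++i) {
    const double gx = G(i, 0), gy = G(i, 1), gz = G(i, 2);
    B(0, 3 * i) = gx;
    B(1, 3 * i + 1) = gy;
    B(2, 3 * i + 2) = gz;
    B(3, 3 * i) = gy; B(3, 3 * i + 1) = gx;
    B(4, 3 * i + 1) = gz; B(4, 3 * i + 2) = gy;
    B(5, 3 * i) = gz; B(5, 3 * i + 2) = gx;
  }
}

// Assemble global stiffness as lower-triangle triplets (1-based dof indices).
// [[Rcpp::export]]
List tet10_assemble(const arma::mat& nodes, const IntegerMatrix& elems,
                    const arma::vec& Evec, const arma::vec& nuvec) {
  const int m = elems.nrow();
  const R_xlen_t per = 465; // 30*31/2
  IntegerVector ti((R_xlen_t)m * per), tj((R_xlen_t)m * per);
  NumericVector tx((R_xlen_t)m * per);

  arma::mat::fixed<10, 3> dN[4];
  double L[4];
  for (int g = 0; g < 4; ++g) { gauss_bary(g, L); shape_dN(L, dN[g]); }

  arma::mat::fixed<3, 3> Jinv;
  arma::mat::fixed<6, 6> D;
  arma::mat::fixed<6, 30> B;
  arma::mat::fixed<30, 30> Ke;
  int dof[30];

  R_xlen_t k = 0;
  for (int e = 0; e < m; ++e) {
    const double detJ = corner_jacobian(nodes, elems, e, Jinv);
    if (detJ <= 0) stop("inverted or degenerate element (id %d, detJ = %g)", e + 1, detJ);
    material_D(Evec[e], nuvec[e], D);
    Ke.zeros();
    const double w = detJ / 24.0; // (1/4 weight) * (1/6 reference volume) * detJ ... detJ/6 is volume
    for (int g = 0; g < 4; ++g) {
      arma::mat::fixed<10, 3> G = dN[g] * Jinv;
      fill_B(G, B);
      Ke += w * (B.t() * (D * B));
    }
    for (int i = 0; i < 10; ++i) {
      const int base = 3 * (elems(e, i) - 1);
      dof[3 * i] = base + 1; dof[3 * i + 1] = base + 2; dof[3 * i + 2] = base + 3;
    }
    for (int a = 0; a < 30; ++a) {
      for (int b = 0; b <= a; ++b) {
        int ia = dof[a], ib = dof[b];
        if (ia < ib) { int t = ia; ia = ib; ib = t; }
        ti[k] = ia; tj[k] = ib; tx[k] = Ke(a, b);
        ++k;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Stresses, integration weights and physical coordinates at the 4 Gauss
// points of every element.  Returns sigma (m x 24: 4 points x 6 Voigt),
// wdet (m x 4) and pts (m x 12).
// [[Rcpp::export]]
List tet10_stress(const arma::mat& nodes, const IntegerMatrix& elems,
                  const arma::vec& Evec, const arma::vec& nuvec,
                  const arma::vec& U) {
  const int m = elems.nrow();
  arma::mat sig(m, 24), wdet(m, 4), pts(m, 12);

  arma::mat::fixed<10, 3> dN[4];
  double Ng[4][10];
  double L[4];
  for (int g = 0; g < 4; ++g) {
    gauss_bary(g, L);
    shape_dN(L, dN[g]);
    shape_N(L, Ng[g]);
  }

  arma::mat::fixed<3, 3> Jinv;
  arma::mat::fixed<6, 6> D;
  arma::mat::fixed<6, 30> B;
  arma::vec::fixed<30> ue;

  for (int e = 0; e < m; ++e) {
    const double detJ = corner_jacobian(nodes, elems, e, Jinv);
    material_D(Evec[e], nuvec[e], D);
    for (int i = 0; i < 10; ++i) {
      const int base = 3 * (elems(e, i) - 1);
      ue[3 * i] = U[base]; ue[3 * i + 1] = U[base + 1]; ue[3 * i + 2] = U[base + 2];
    }
    for (int g = 0; g < 4; ++g) {
      arma::mat::fixed<10, 3> G = dN[g] * Jinv;
      fill_B(G, B);
      arma::vec::fixed<6> s = D * (B * ue);
      for (int c = 0; c < 6; ++c) sig(e, 6 * g + c) = s[c];
      wdet(e, g) = detJ / 24.0;
      double x = 0, y = 0, z = 0;
      for (int i = 0; i < 10; ++i) {
        const int n = elems(e, i) - 1;
        x += Ng[g][i] * nodes(n, 0);
        y += Ng[g][i] * nodes(n, 1);
        z += Ng[g][i] * nodes(n, 2);
      }
      pts(e, 3 * g) = x; pts(e, 3 * g + 1) = y; pts(e, 3 * g + 2) = z;
    }
  }
  return List::create(_["sigma"] = sig, _["wdet"] = wdet, _["pts"] = pts);
}

// [[Rcpp::export]]
arma::vec tet10_volumes(const arma::mat& nodes, const IntegerMatrix& elems) {
  const int m = elems.nrow();
  arma::vec v(m);
  arma::mat::fixed<3, 3> Jinv;
  for (int e = 0; e < m; ++e) v[e] = corner_jacobian(nodes, elems, e, Jinv) / 6.0;
  return v;
}

// Normalized shape quality: 6*sqrt(2)*V / l_rms^3 (1 for the regular tet,
// <= 0 for inverted elements).
// [[Rcpp::export]]
arma::vec tet_quality(const arma::mat& nodes, const IntegerMatrix& elems) {
  const int m = elems.nrow();
  arma::vec q(m);
  const int ed[6][2] = {{0, 1}, {1, 2}, {0, 2}, {0, 3}, {1, 3}, {2, 3}};
  arma::mat::fixed<3, 3> Jinv;
  for (int e = 0; e < m; ++e) {
    const double V = corner_jacobian(nodes, elems, e, Jinv) / 6.0;
    double s = 0;
    for (int k = 0; k < 6; ++k) {
      double l2 = 0;
      for (int d = 0; d < 3; ++d) {
        const double dd = nodes(elems(e, ed[k][0]) - 1, d) - nodes(elems(e, ed[k][1]) - 1, d);
        l2 += dd * dd;
      }
      s += l2;
    }
    const double lrms = std::sqrt(s / 6.0);
    q[e] = 6.0 * std::sqrt(2.0) * V / (lrms * lrms * lrms);
  }
  return q;
}

// Volume-weighted nodal averaging of element-mean stresses (simple
// Zienkiewicz-Zhu recovery).  sraw is m x 24 Gauss stresses.
// [[Rcpp::export]]
arma::mat tet10_recover_avg(const arma::mat& nodes, const IntegerMatrix& elems,
                            const arma::mat& sraw) {
  const int n = nodes.n_rows, m = elems.nrow();
  arma::mat num(n, 6, arma::fill::zeros);
  arma::vec den(n, arma::fill::zeros);
  arma::mat::fixed<3, 3> Jinv;
  for (int e = 0; e < m; ++e) {
    const double V = corner_jacobian(nodes, elems, e, Jinv) / 6.0;
    double mean[6];
    for (int c = 0; c < 6; ++c) {
      mean[c] = 0.25 * (sraw(e, c) + sraw(e, 6 + c) + sraw(e, 12 + c) + sraw(e, 18 + c));
    }
    for (int i = 0; i < 10; ++i) {
      const int nd = elems(e, i) - 1;
      for (int c = 0; c < 6; ++c) num(nd, c) += V * mean[c];
      den[nd] += V;
    }
  }
  for (int nd = 0; nd < n; ++nd) {
    if (den[nd] > 0) for (int c = 0; c < 6; ++c) num(nd, c) /= den[nd];
    else for (int c = 0; c < 6; ++c) num(nd, c) = NA_REAL;
  }
  return num;
}

// Superconvergent-patch style recovery: per node, least-squares linear fit
// (1, x, y, z) through the Gauss values of adjacent elements, evaluated at
// the node.  Falls back to averaged value when the patch is too small or
// ill-conditioned.
// [[Rcpp::export]]
arma::mat tet10_recover_spr(const arma::mat& nodes, const IntegerMatrix& elems,
                            const arma::mat& sraw, const arma::mat& pts,
                            const arma::mat& fallback) {
  const int n = nodes.n_rows, m = elems.nrow();
  // node -> element adjacency (CSR)
  std::vector<int> cnt(n, 0);
  for (int e = 0; e < m; ++e)
    for (int i = 0; i < 10; ++i) cnt[elems(e, i) - 1]++;
  std::vector<int> start(n + 1, 0);
  for (int v = 0; v < n; ++v) start[v + 1] = start[v] + cnt[v];
  std::vector<int> adj(start[n]);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < m; ++e)
    for (int i = 0; i < 10; ++i) {
      const int v = elems(e, i) - 1;
      adj[start[v] + fill[v]++] = e;
    }

  arma::mat out(n, 6);
  arma::mat::fixed<4, 4> A;
  arma::mat::fixed<4, 6> rhs;
  for (int v = 0; v < n; ++v) {
    const int ne = start[v + 1] - start[v];
    if (ne < 2) { out.row(v) = fallback.row(v); continue; }
    A.zeros(); rhs.zeros();
    const double x0 = nodes(v, 0), y0 = nodes(v, 1), z0 = nodes(v, 2);
    double scale = 0;
    for (int k = start[v]; k < start[v + 1]; ++k) {
      const int e = adj[k];
      for (int g = 0; g < 4; ++g) {
        const double dx = pts(e, 3 * g) - x0, dy = pts(e, 3 * g + 1) - y0,
                     dz = pts(e, 3 * g + 2) - z0;
        scale = std::max(scale, std::abs(dx) + std::abs(dy) + std::abs(dz));
      }
    }
    if (scale <= 0) { out.row(v) = fallback.row(v); continue; }
    for (int k = start[v]; k < start[v + 1]; ++k) {
      const int e = adj[k];
      for (int g = 0; g < 4; ++g) {
        const double p[4] = {1.0, (pts(e, 3 * g) - x0) / scale,
                             (pts(e, 3 * g + 1) - y0) / scale,
                             (pts(e, 3 * g + 2) - z0) / scale};
        for (int a = 0; a < 4; ++a) {
          for (int b = 0; b < 4; ++b) A(a, b) += p[a] * p[b];
          for (int c = 0; c < 6; ++c) rhs(a, c) += p[a] * sraw(e, 6 * g + c);
        }
      }
    }
    arma::mat::fixed<4, 6> coef;
    const bool ok = arma::solve(coef, A, rhs, arma::solve_opts::no_approx);
    if (!ok || arma::rcond(A) < 1e-10) { out.row(v) = fallback.row(v); continue; }
    for (int c = 0; c < 6; ++c) out(v, c) = coef(0, c); // value at the node itself
  }
  return out;
}

// Element integrals for the Zienkiewicz-Zhu energy error norm:
// err_e = int (s* - sh)' Cinv (s* - sh) dV,  ust_e = int s*' Cinv s* dV,
// with s* interpolated from nodal recovered stresses via tet10 shapes.
// [[Rcpp::export]]
arma::mat tet10_zz_integrals(const arma::mat& nodes, const IntegerMatrix& elems,
                             const arma::vec& Evec, const arma::vec& nuvec,
                             const arma::mat& sraw, const arma::mat& snod) {
  const int m = elems.nrow();
  arma::mat out(m, 2, arma::fill::zeros);
  double Ng[4][10], L[4];
  for (int g = 0; g < 4; ++g) { gauss_bary(g, L); shape_N(L, Ng[g]); }
  arma::mat::fixed<3, 3> Jinv;
  arma::mat::fixed<6, 6> S;
  for (int e = 0; e < m; ++e) {
    const double detJ = corner_jacobian(nodes, elems, e, Jinv);
    material_Cinv(Evec[e], nuvec[e], S);
    const double w = detJ / 24.0;
    for (int g = 0; g < 4; ++g) {
      arma::vec::fixed<6> sh, st;
      st.zeros();
      for (int c = 0; c < 6; ++c) sh[c] = sraw(e, 6 * g + c);
      for (int i = 0; i < 10; ++i) {
        const int nd = elems(e, i) - 1;
        for (int c = 0; c < 6; ++c) st[c] += Ng[g][i] * snod(nd, c);
      }
      arma::vec::fixed<6> d = st - sh;
      out(e, 0) += w * arma::dot(d, S * d);
      out(e, 1) += w * arma::dot(st, S * st);
    }
  }
  return out;
}

// ---- point location and interpolation -------------------------------------

struct LocGrid {
  double lo[3], h[3];
  int nb[3];
  std::vector<std::vector<int>> cells;
};

static void grid_build(const arma::mat& nodes, const IntegerMatrix& elems,
                       LocGrid& G) {
  const int m = elems.nrow();
  double hi[3];
  for (int d = 0; d < 3; ++d) { G.lo[d] = nodes.col(d).min(); hi[d] = nodes.col(d).max(); }
  const int target = std::max(1, (int)std::floor(std::cbrt((double)m / 4.0)));
  for (int d = 0; d < 3; ++d) {
    G.nb[d] = std::max(1, target);
    G.h[d] = (hi[d] - G.lo[d]) / G.nb[d];
    if (G.h[d] <= 0) { G.h[d] = 1; G.nb[d] = 1; }
  }
  G.cells.assign((size_t)G.nb[0] * G.nb[1] * G.nb[2], {});
  for (int e = 0; e < m; ++e) {
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < 4; ++i) {
      const int nd = elems(e, i) - 1;
      for (int d = 0; d < 3; ++d) {
        mn[d] = std::min(mn[d], nodes(nd, d));
        mx[d] = std::max(mx[d], nodes(nd, d));
      }
    }
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = std::max(0, std::min(G.nb[d] - 1, (int)((mn[d] - G.lo[d]) / G.h[d])));
      i1[d] = std::max(0, std::min(G.nb[d] - 1, (int)((mx[d] - G.lo[d]) / G.h[d])));
    }
    for (int a = i0[0]; a <= i1[0]; ++a)
      for (int b = i0[1]; b <= i1[1]; ++b)
        for (int c = i0[2]; c <= i1[2]; ++c)
          G.cells[(size_t)a + G.nb[0] * ((size_t)b + (size_t)G.nb[1] * c)].push_back(e);
  }
}

// barycentric coordinates of p wrt corner tet of element e
static bool bary_in(const arma::mat& nodes, const IntegerMatrix& elems, int e,
                    const double p[3], double tol, double Lout[4]) {
  arma::mat::fixed<3, 3> J;
  const int n1 = elems(e, 0) - 1;
  arma::vec::fixed<3> r;
  for (int d = 0; d < 3; ++d) {
    for (int c = 0; c < 3; ++c) J(d, c) = nodes(elems(e, c + 1) - 1, d) - nodes(n1, d);
    r[d] = p[d] - nodes(n1, d);
  }
  arma::vec::fixed<3> xi;
  if (!arma::solve(xi, J, r, arma::solve_opts::no_approx)) return false;
  const double L1 = 1 - xi[0] - xi[1] - xi[2];
  if (L1 < -tol || xi[0] < -tol || xi[1] < -tol || xi[2] < -tol) return false;
  Lout[0] = L1; Lout[1] = xi[0]; Lout[2] = xi[1]; Lout[3] = xi[2];
  return true;
}

// Interpolate nodal field `vals` (n x q) at query points (k x 3) using tet10
// shape functions.  Returns k x q matrix plus a `found` flag column handled
// in R via the attribute.
// [[Rcpp::export]]
List tet10_interp(const arma::mat& nodes, const IntegerMatrix& elems,
                  const arma::mat& vals, const arma::mat& query, double tol) {
  LocGrid G;
  grid_build(nodes, elems, G);
  const int k = query.n_rows, q = vals.n_cols;
  arma::mat out(k, q, arma::fill::zeros);
  LogicalVector found(k);
  double L[4], N[10];
  for (int p = 0; p < k; ++p) {
    const double pt[3] = {query(p, 0), query(p, 1), query(p, 2)};
    int ic[3];
    bool inside = true;
    for (int d = 0; d < 3; ++d) {
      ic[d] = (int)((pt[d] - G.lo[d]) / G.h[d]);
      if (ic[d] < -1 || ic[d] > G.nb[d]) inside = false;
      ic[d] = std::max(0, std::min(G.nb[d] - 1, ic[d]));
    }
    bool ok = false;
    if (inside) {
      // search the cell and (if needed) its neighbours with growing tolerance
      for (int pass = 0; pass < 2 && !ok; ++pass) {
        const int rad = pass;
        const double tl = pass == 0 ? tol : 100 * tol;
        for (int a = std::max(0, ic[0] - rad); a <= std::min(G.nb[0] - 1, ic[0] + rad) && !ok; ++a)
          for (int b = std::max(0, ic[1] - rad); b <= std::min(G.nb[1] - 1, ic[1] + rad) && !ok; ++b)
            for (int c = std::max(0, ic[2] - rad); c <= std::min(G.nb[2] - 1, ic[2] + rad) && !ok; ++c) {
              const std::vector<int>& lst =
                G.cells[(size_t)a + G.nb[0] * ((size_t)b + (size_t)G.nb[1] * c)];
              for (size_t t = 0; t < lst.size(); ++t) {
                const int e = lst[t];
                if (bary_in(nodes, elems, e, pt, tl, L)) {
                  shape_N(L, N);
                  for (int cc = 0; cc < q; ++cc) {
                    double s = 0;
                    for (int i = 0; i < 10; ++i) s += N[i] * vals(elems(e, i) - 1, cc);
                    out(p, cc) = s;
                  }
                  ok = true;
                  break;
                }
              }
            }
      }
    }
    found[p] = ok;
  }
  return List::create(_["values"] = out, _["found"] = found);
}

// ---- point-to-triangle-soup distance ---------------------------------------

static double dist_point_tri(const double p[3], const double a[3],
                             const double b[3], const double c[3]) {
  // Eberly-style closest point on triangle
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u, v;
  if (d1 <= 0 && d2 <= 0) { u = 0; v = 0; }
  else {
    double bp[3], cp[3];
    for (int d = 0; d < 3; ++d) { bp[d] = p[d] - b[d]; cp[d] = p[d] - c[d]; }
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0 && d4 <= d3) { u = 1; v = 0; }
    else if (d6 >= 0 && d5 <= d6) { u = 0; v = 1; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      const double vb = d5 * d2 - d1 * d6;
      const double va = d3 * d6 - d5 * d4;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) { u = d1 / (d1 - d3); v = 0; }
      else if (vb <= 0 && d2 >= 0 && d6 <= 0) { u = 0; v = d2 / (d2 - d6); }
      else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        u = 1 - w; v = w;
      } else {
        const double den = 1.0 / (va + vb + vc);
        u = vb * den; v = vc * den;
      }
    }
  }
  double dd = 0;
  for (int d = 0; d < 3; ++d) {
    const double q = a[d] + u * ab[d] + v * ac[d] - p[d];
    dd += q * q;
  }
  return std::sqrt(dd);
}

// Minimum distance from each query point to a triangle soup (k x 3 vertex
// index matrix into verts).  Grid-accelerated with expanding search.
// [[Rcpp::export]]
arma::vec min_tri_distance(const arma::mat& verts, const IntegerMatrix& tris,
                           const arma::mat& query) {
  const int nt = tris.nrow(), np = query.n_rows;
  // centroids + bounding radius per triangle
  arma::mat cen(nt, 3);
  arma::vec rad(nt);
  for (int t = 0; t < nt; ++t) {
    double r2 = 0;
    for (int d = 0; d < 3; ++d)
      cen(t, d) = (verts(tris(t, 0) - 1, d) + verts(tris(t, 1) - 1, d) +
                   verts(tris(t, 2) - 1, d)) / 3.0;
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int d = 0; d < 3; ++d) {
        const double dd = verts(tris(t, i) - 1, d) - cen(t, d);
        s += dd * dd;
      }
      r2 = std::max(r2, s);
    }
    rad[t] = std::sqrt(r2);
  }
  const double rmax = rad.max();
  arma::vec out(np);
  for (int p = 0; p < np; ++p) {
    const double pt[3] = {query(p, 0), query(p, 1), query(p, 2)};
    // lower-bound prune on centroid distance
    double best = 1e300;
    // first pass: find a decent upper bound from nearest centroids
    double bestCen = 1e300;
    int bestT = 0;
    for (int t = 0; t < nt; ++t) {
      double s = 0;
      for (int d = 0; d < 3; ++d) { const double dd = cen(t, d) - pt[d]; s += dd * dd; }
      if (s < bestCen) { bestCen = s; bestT = t; }
    }
    {
      double a[3], b[3], c[3];
      for (int d = 0; d < 3; ++d) {
        a[d] = verts(tris(bestT, 0) - 1, d);
        b[d] = verts(tris(bestT, 1) - 1, d);
        c[d] = verts(tris(bestT, 2) - 1, d);
      }
      best = dist_point_tri(pt, a, b, c);
    }
    const double cut = best + rmax;
    for (int t = 0; t < nt; ++t) {
      double s = 0;
      for (int d = 0; d < 3; ++d) { const double dd = cen(t, d) - pt[d]; s += dd * dd; }
      if (std::sqrt(s) - rad[t] >= best) continue;
      if (std::sqrt(s) > cut + rad[t]) continue;
      double a[3], b[3], c[3];
      for (int d = 0; d < 3; ++d) {
        a[d] = verts(tris(t, 0) - 1, d);
        b[d] = verts(tris(t, 1) - 1, d);
        c[d] = verts(tris(t, 2) - 1, d);
      }
      const double dd = dist_point_tri(pt, a, b, c);
      if (dd < best) best = dd;
    }
    out[p] = best;
  }
  return out;
}
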