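// Matrix-free structured-grid solver for the static Navier equation
//   G lap(u) + (G/(1-2 nu)) grad(div u) + F = 0
// discretized with trilinear hexahedral elements on a regular grid.
// The material is spatially uniform, so one 24x24 element stiffness
// (assembled on the R side, with selective reduced integration on the
// div-div term) serves every element; the global operator is applied
// element-by-element and the system is solved with Jacobi-preconditioned
// conjugate gradients.
//
// Node numbering: node = ix + nx*(iy + ny*iz), 0-based; dofs (ux,uy,uz)
// interleaved: dof = 3*node + c.  Element corner order: dx fastest, then
// dy, then dz — (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  int nodeOffs[8];
  Grid(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_) {
    int k = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx)
          nodeOffs[k++] = dx + nx * (dy + ny * dz);
  }
  inline long nnode() const { return (long)nx * ny * nz; }
  inline long ndof() const { return 3L * nnode(); }
};

// y = K x over the whole grid (no boundary handling).
void applyK(const Grid& g, const double* Ke, const double* x, double* y) {
  const long ndof = g.ndof();
  std::memset(y, 0, sizeof(double) * ndof);
  const int ex = g.nx - 1, ey = g.ny - 1, ez = g.nz - 1;
  double xl[24], yl[24];
  int dof[24];
  for (int iz = 0; iz < ez; ++iz) {
    for (int iy = 0; iy < ey; ++iy) {
      long nrow = (long)g.nx * (iy + (long)g.ny * iz);
      for (int ix = 0; ix < ex; ++ix) {
        long n0 = ix + nrow;
        for (int c = 0; c < 8; ++c) {
          long n = n0 + g.nodeOffs[c];
          dof[3 * c] = 3 * n;
          dof[3 * c + 1] = 3 * n + 1;
          dof[3 * c + 2] = 3 * n + 2;
        }
        for (int a = 0; a < 24; ++a) xl[a] = x[dof[a]];
        for (int a = 0; a < 24; ++a) yl[a] = 0.0;
        for (int b = 0; b < 24; ++b) {
          const double xb = xl[b];
          if (xb == 0.0) continue;
          const double* col = Ke + 24 * b;  // column-major, symmetric
          for (int a = 0; a < 24; ++a) yl[a] += col[a] * xb;
        }
        for (int a = 0; a < 24; ++a) y[dof[a]] += yl[a];
      }
    }
  }
}

void assembleDiag(const Grid& g, const double* Ke, double* d) {
  const long ndof = g.ndof();
  std::memset(d, 0, sizeof(double) * ndof);
  const int ex = g.nx - 1, ey = g.ny - 1, ez = g.nz - 1;
  for (int iz = 0; iz < ez; ++iz)
    for (int iy = 0; iy < ey; ++iy)
      for (int ix = 0; ix < ex; ++ix) {
        long n0 = ix + (long)g.nx * (iy + (long)g.ny * iz);
        for (int c = 0; c < 8; ++c) {
          long n = n0 + g.nodeOffs[c];
          for (int cc = 0; cc < 3; ++cc) {
            int a = 3 * c + cc;
            d[3 * n + cc] += Ke[a + 24 * a];
          }
        }
      }
}

inline void maskFixed(const int* fixedIdx, int nfixed, double* v) {
  for (int i = 0; i < nfixed; ++i) v[fixedIdx[i]] = 0.0;
}

}  // namespace

// Apply the (unconstrained) discrete Navier operator: returns K %*% u.
// Used by tests to check discrete residuals and superposition.
// [[Rcpp::export(name = ".navier3d_apply")]]
NumericVector navier3d_apply(NumericVector u, NumericMatrix Ke,
                             int nx, int ny, int nz) {
  Grid g(nx, ny, nz);
  if ((long)u.size() != g.ndof()) stop("u has wrong length");
  if (Ke.nrow() != 24 || Ke.ncol() != 24) stop("Ke must be 24 x 24");
  NumericVector y(g.ndof());
  applyK(g, Ke.begin(), u.begin(), y.begin());
  return y;
}

// Jacobi-preconditioned CG for K u = f with Dirichlet dofs held at u0.
// fixed_idx: 0-based dof indices of constrained dofs; u0 full-length
// vector carrying prescribed values there (zeros elsewhere is typical).
// [[Rcpp::export(name = ".navier3d_cg")]]
List navier3d_cg(NumericVector f, NumericMatrix Ke, int nx, int ny, int nz,
                 IntegerVector fixed_idx, NumericVector u0,
                 double tol, int maxit) {
  Grid g(nx, ny, nz);
  const long n = g.ndof();
  if ((long)f.size() != n || (long)u0.size() != n) stop("bad vector length");
  if (Ke.nrow() != 24 || Ke.ncol() != 24) stop("Ke must be 24 x 24");
  const int nfixed = fixed_idx.size();
  std::vector<int> fx(fixed_idx.begin(), fixed_idx.end());

  // rhs on free dofs: b = f - K u0, zeroed on fixed dofs
  std::vector<double> b(n), tmp(n);
  applyK(g, Ke.begin(), u0.begin(), tmp.data());
  for (long i = 0; i < n; ++i) b[i] = f[i] - tmp[i];
  maskFixed(fx.data(), nfixed, b.data());

  // Jacobi preconditioner (unit on fixed dofs)
  std::vector<double> dinv(n);
  assembleDiag(g, Ke.begin(), dinv.data());
  for (long i = 0; i < n; ++i) dinv[i] = dinv[i] > 0 ? 1.0 / dinv[i] : 1.0;

  std::vector<double> x(n, 0.0), r(b), z(n), p(n), Ap(n);
  double bnorm = 0.0;
  for (long i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  double relres = 1.0;
  int iter = 0;
  if (bnorm == 0.0) {
    relres = 0.0;
  } else {
    for (long i = 0; i < n; ++i) z[i] = dinv[i] * r[i];
    p = z;
    double rz = 0.0;
    for (long i = 0; i < n; ++i) rz += r[i] * z[i];
    for (iter = 1; iter <= maxit; ++iter) {
      // Ap = K p restricted to free dofs
      applyK(g, Ke.begin(), p.data(), Ap.data());
      maskFixed(fx.data(), nfixed, Ap.data());
      double pAp = 0.0;
      for (long i = 0; i < n; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) stop("CG breakdown: operator not positive definite");
      double alpha = rz / pAp;
      double rnorm = 0.0;
      for (long i = 0; i < n; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm += r[i] * r[i];
      }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres < tol) break;
      double rznew = 0.0;
      for (long i = 0; i < n; ++i) {
        z[i] = dinv[i] * r[i];
        rznew += r[i] * z[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (long i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
      if (iter % 200 == 0) Rcpp::checkUserInterrupt();
    }
    if (iter > maxit) iter = maxit;
  }

  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = x[i] + u0[i];
  return List::create(_["u"] = out, _["iterations"] = iter,
                      _["relative_residual"] = relres,
                      _["converged"] = (relres < tol));
}
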