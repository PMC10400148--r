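// Conjugate-gradient solver for the finite-volume diffusion operator on a
// structured voxel grid, preconditioned with symmetric Gauss-Seidel (SSOR
// with omega = 1), which handles the strong conductance contrasts between
// gas, liquid, and membrane-limited faces far better than Jacobi scaling.
// Face conductances: gx[i,j,k] couples voxel (i,j,k) to (i+1,j,k); likewise
// gy, gz. Dirichlet cells are eliminated symmetrically.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz, n, nxy;
  const double *gx, *gy, *gz;
};

// y = A x over free cells (fixed cells give y = 0 and do not couple)
void apply_A(const Grid &G, const std::vector<double> &diag,
             const std::vector<char> &fixed, const double *x, double *y) {
  const int nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;
  const double *gx = G.gx, *gy = G.gy, *gz = G.gz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nxy;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        if (fixed[id]) { y[id] = 0.0; continue; }
        double acc = diag[id] * x[id];
        if (i > 0) acc -= gx[id - 1] * x[id - 1];
        if (i < nx - 1) acc -= gx[id] * x[id + 1];
        if (j > 0) acc -= gy[id - nx] * x[id - nx];
        if (j < ny - 1) acc -= gy[id] * x[id + nx];
        if (k > 0) acc -= gz[id - nxy] * x[id - nxy];
        if (k < nz - 1) acc -= gz[id] * x[id + nxy];
        y[id] = acc;
      }
    }
}

// z = M^{-1} r with M = (D - L) D^{-1} (D - U), L/U the lower/upper
// conductance couplings. Fixed cells stay zero (their couplings were
// zeroed by setting x = 0 there and moving contributions into the rhs).
void apply_ssor(const Grid &G, const std::vector<double> &diag,
                const std::vector<char> &fixed, const double *r,
                std::vector<double> &y, double *z) {
  const int nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;
  const double *gx = G.gx, *gy = G.gy, *gz = G.gz;
  // forward: (D - L) y = r
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nxy;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        if (fixed[id] || diag[id] <= 0) { y[id] = 0.0; continue; }
        double s = r[id];
        if (i > 0) s += gx[id - 1] * y[id - 1];
        if (j > 0) s += gy[id - nx] * y[id - nx];
        if (k > 0) s += gz[id - nxy] * y[id - nxy];
        y[id] = s / diag[id];
      }
    }
  // backward: (D - U) z = D y
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j) {
      int base = j * nx + k * nxy;
      for (int i = nx - 1; i >= 0; --i) {
        int id = base + i;
        if (fixed[id] || diag[id] <= 0) { z[id] = 0.0; continue; }
        double s = diag[id] * y[id];
        if (i < nx - 1) s += gx[id] * z[id + 1];
        if (j < ny - 1) s += gy[id] * z[id + nx];
        if (k < nz - 1) s += gz[id] * z[id + nxy];
        z[id] = s / diag[id];
      }
    }
}

}  // namespace

// [[Rcpp::export]]
List cg_solve_cpp(IntegerVector dims, NumericVector gx, NumericVector gy,
                  NumericVector gz, NumericVector diag_extra,
                  NumericVector rhs, LogicalVector fixed_mask,
                  NumericVector fixed_values, NumericVector x0,
                  double tol = 1e-10, int maxit = 20000) {
  Grid G;
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.n = G.nx * G.ny * G.nz;
  G.nxy = G.nx * G.ny;
  G.gx = gx.begin(); G.gy = gy.begin(); G.gz = gz.begin();
  const int n = G.n, nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;

  std::vector<char> fixed(n);
  for (int i = 0; i < n; ++i) fixed[i] = fixed_mask[i] ? 1 : 0;

  // zero couplings into fixed cells: copy conductance arrays and clear the
  // faces touching fixed cells (their flux contribution moves to the rhs)
  std::vector<double> gxv(gx.begin(), gx.end());
  std::vector<double> gyv(gy.begin(), gy.end());
  std::vector<double> gzv(gz.begin(), gz.end());
  std::vector<double> b(rhs.begin(), rhs.end());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + j * nx + k * nxy;
        if (i < nx - 1) {
          int nb = id + 1;
          if (fixed[id] != fixed[nb]) {
            int fr = fixed[id] ? id : nb, fl = fixed[id] ? nb : id;
            b[fl] += gxv[id] * fixed_values[fr];
          }
          if (fixed[id] || fixed[nb]) gxv[id] = 0.0;
        }
        if (j < ny - 1) {
          int nb = id + nx;
          if (fixed[id] != fixed[nb]) {
            int fr = fixed[id] ? id : nb, fl = fixed[id] ? nb : id;
            b[fl] += gyv[id] * fixed_values[fr];
          }
          if (fixed[id] || fixed[nb]) gyv[id] = 0.0;
        }
        if (k < nz - 1) {
          int nb = id + nxy;
          if (fixed[id] != fixed[nb]) {
            int fr = fixed[id] ? id : nb, fl = fixed[id] ? nb : id;
            b[fl] += gzv[id] * fixed_values[fr];
          }
          if (fixed[id] || fixed[nb]) gzv[id] = 0.0;
        }
      }

  // diagonal: original face sums (including faces to fixed cells) + extra.
  // Using the original sums keeps the eliminated system SPD.
  std::vector<double> diag(n, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + j * nx + k * nxy;
        double dsum = diag_extra[id];
        if (i > 0) dsum += gx[id - 1];
        if (i < nx - 1) dsum += gx[id];
        if (j > 0) dsum += gy[id - nx];
        if (j < ny - 1) dsum += gy[id];
        if (k > 0) dsum += gz[id - nxy];
        if (k < nz - 1) dsum += gz[id];
        diag[id] = dsum;
      }

  Grid Gel = G;  // eliminated system uses the cleared conductances
  Gel.gx = gxv.data(); Gel.gy = gyv.data(); Gel.gz = gzv.data();

  std::vector<double> x(n), r(n), z(n), p(n), Ap(n), ywork(n);
  for (int i = 0; i < n; ++i) x[i] = fixed[i] ? 0.0 : x0[i];

  apply_A(Gel, diag, fixed, x.data(), Ap.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    if (fixed[i]) { r[i] = 0.0; continue; }
    r[i] = b[i] - Ap[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  double ref = bnorm > 0 ? bnorm : 1.0;

  apply_ssor(Gel, diag, fixed, r.data(), ywork, z.data());
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    if (fixed[i]) { z[i] = 0.0; p[i] = 0.0; continue; }
    p[i] = z[i];
    rz += r[i] * z[i];
  }

  int it = 0;
  double relres = 0.0;
  for (; it < maxit; ++it) {
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
    relres = std::sqrt(rnorm) / ref;
    if (relres <= tol) break;
    apply_A(Gel, diag, fixed, p.data(), Ap.data());
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
    }
    apply_ssor(Gel, diag, fixed, r.data(), ywork, z.data());
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) if (!fixed[i]) rz_new += r[i] * z[i];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = fixed[i] ? 0.0 : z[i] + beta * p[i];
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fixed[i] ? fixed_values[i] : x[i];
  return List::create(_["x"] = out, _["iterations"] = it,
                      _["relres"] = relres);
}
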