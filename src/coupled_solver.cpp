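// BiCGStab solver for the coupled CO2/HCO3- finite-volume system with the
// local carbonic-anhydrase exchange Jacobian implicit as 2x2 voxel blocks,
// preconditioned with a block symmetric Gauss-Seidel sweep. This removes
// the stiff-splitting failure mode of solving the two species separately:
// CA exchanges the pair orders of magnitude faster than diffusion moves
// either one.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct CGrid { int nx, ny, nz, nxy, n; };

struct Sp {
  const double *gx, *gy, *gz;   // cleared face conductances
  std::vector<double> diag;     // face sums + own-species coupling diagonal
  const char *fixed;
};

void apply_block(const CGrid &G, const Sp &A, const Sp &B,
                 const double *dCB, const double *dBC,
                 const double *xC, const double *xB,
                 double *yC, double *yB) {
  const int nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nxy;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        double aC = 0.0, aB = 0.0;
        if (!A.fixed[id]) {
          aC = A.diag[id] * xC[id] + dCB[id] * xB[id];
          if (i > 0) aC -= A.gx[id - 1] * xC[id - 1];
          if (i < nx - 1) aC -= A.gx[id] * xC[id + 1];
          if (j > 0) aC -= A.gy[id - nx] * xC[id - nx];
          if (j < ny - 1) aC -= A.gy[id] * xC[id + nx];
          if (k > 0) aC -= A.gz[id - nxy] * xC[id - nxy];
          if (k < nz - 1) aC -= A.gz[id] * xC[id + nxy];
        }
        if (!B.fixed[id]) {
          aB = B.diag[id] * xB[id] + dBC[id] * xC[id];
          if (i > 0) aB -= B.gx[id - 1] * xB[id - 1];
          if (i < nx - 1) aB -= B.gx[id] * xB[id + 1];
          if (j > 0) aB -= B.gy[id - nx] * xB[id - nx];
          if (j < ny - 1) aB -= B.gy[id] * xB[id + nx];
          if (k > 0) aB -= B.gz[id - nxy] * xB[id - nxy];
          if (k < nz - 1) aB -= B.gz[id] * xB[id + nxy];
        }
        yC[id] = aC;
        yB[id] = aB;
      }
    }
}

// z = M^{-1} r with M = (D - L) D^{-1} (D - U), D the 2x2 block diagonal
void block_ssor(const CGrid &G, const Sp &A, const Sp &B,
                const double *dCB, const double *dBC,
                const double *i00, const double *i01,
                const double *i10, const double *i11,
                const double *rC, const double *rB,
                std::vector<double> &yC, std::vector<double> &yB,
                double *zC, double *zB) {
  const int nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;
  // forward: (D - L) y = r
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nxy;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        double sC = rC[id], sB = rB[id];
        if (i > 0) { sC += A.gx[id - 1] * yC[id - 1]; sB += B.gx[id - 1] * yB[id - 1]; }
        if (j > 0) { sC += A.gy[id - nx] * yC[id - nx]; sB += B.gy[id - nx] * yB[id - nx]; }
        if (k > 0) { sC += A.gz[id - nxy] * yC[id - nxy]; sB += B.gz[id - nxy] * yB[id - nxy]; }
        yC[id] = A.fixed[id] ? 0.0 : i00[id] * sC + i01[id] * sB;
        yB[id] = B.fixed[id] ? 0.0 : i10[id] * sC + i11[id] * sB;
      }
    }
  // backward: (D - U) z = D y
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j) {
      int base = j * nx + k * nxy;
      for (int i = nx - 1; i >= 0; --i) {
        int id = base + i;
        double wC = A.fixed[id] ? 0.0 : A.diag[id] * yC[id] + dCB[id] * yB[id];
        double wB = B.fixed[id] ? 0.0 : B.diag[id] * yB[id] + dBC[id] * yC[id];
        double sC = wC, sB = wB;
        if (i < nx - 1) { sC += A.gx[id] * zC[id + 1]; sB += B.gx[id] * zB[id + 1]; }
        if (j < ny - 1) { sC += A.gy[id] * zC[id + nx]; sB += B.gy[id] * zB[id + nx]; }
        if (k < nz - 1) { sC += A.gz[id] * zC[id + nxy]; sB += B.gz[id] * zB[id + nxy]; }
        zC[id] = A.fixed[id] ? 0.0 : i00[id] * sC + i01[id] * sB;
        zB[id] = B.fixed[id] ? 0.0 : i10[id] * sC + i11[id] * sB;
      }
    }
}

}  // namespace

// [[Rcpp::export]]
List coupled_solve_cpp(IntegerVector dims,
                       NumericVector gxC, NumericVector gyC, NumericVector gzC,
                       NumericVector gxB, NumericVector gyB, NumericVector gzB,
                       NumericVector dCC, NumericVector dCB,
                       NumericVector dBC, NumericVector dBB,
                       NumericVector rhsC, NumericVector rhsB,
                       LogicalVector fixedC_in, LogicalVector fixedB_in,
                       NumericVector fixvC, NumericVector fixvB,
                       NumericVector x0C, NumericVector x0B,
                       double tol = 1e-10, int maxit = 20000) {
  CGrid G;
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.nxy = G.nx * G.ny; G.n = G.nxy * G.nz;
  const int n = G.n, nx = G.nx, ny = G.ny, nz = G.nz, nxy = G.nxy;

  std::vector<char> fC(n), fB(n);
  for (int i = 0; i < n; ++i) {
    fC[i] = fixedC_in[i] ? 1 : 0;
    fB[i] = fixedB_in[i] ? 1 : 0;
  }

  // clear faces touching fixed cells, moving their flux into the rhs
  std::vector<double> gxCv(gxC.begin(), gxC.end()), gyCv(gyC.begin(), gyC.end()),
      gzCv(gzC.begin(), gzC.end());
  std::vector<double> gxBv(gxB.begin(), gxB.end()), gyBv(gyB.begin(), gyB.end()),
      gzBv(gzB.begin(), gzB.end());
  std::vector<double> bC(rhsC.begin(), rhsC.end()), bB(rhsB.begin(), rhsB.end());
  auto eliminate = [&](std::vector<double> &gx, std::vector<double> &gy,
                       std::vector<double> &gz, std::vector<double> &b,
                       const std::vector<char> &fx, NumericVector fixv) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = i + j * nx + k * nxy;
          if (i < nx - 1) {
            int nb = id + 1;
            if (fx[id] != fx[nb]) {
              int fr = fx[id] ? id : nb, fl = fx[id] ? nb : id;
              b[fl] += gx[id] * fixv[fr];
            }
            if (fx[id] || fx[nb]) gx[id] = 0.0;
          }
          if (j < ny - 1) {
            int nb = id + nx;
            if (fx[id] != fx[nb]) {
              int fr = fx[id] ? id : nb, fl = fx[id] ? nb : id;
              b[fl] += gy[id] * fixv[fr];
            }
            if (fx[id] || fx[nb]) gy[id] = 0.0;
          }
          if (k < nz - 1) {
            int nb = id + nxy;
            if (fx[id] != fx[nb]) {
              int fr = fx[id] ? id : nb, fl = fx[id] ? nb : id;
              b[fl] += gz[id] * fixv[fr];
            }
            if (fx[id] || fx[nb]) gz[id] = 0.0;
          }
        }
  };
  eliminate(gxCv, gyCv, gzCv, bC, fC, fixvC);
  eliminate(gxBv, gyBv, gzBv, bB, fB, fixvB);

  Sp A, Bsp;
  A.gx = gxCv.data(); A.gy = gyCv.data(); A.gz = gzCv.data(); A.fixed = fC.data();
  Bsp.gx = gxBv.data(); Bsp.gy = gyBv.data(); Bsp.gz = gzBv.data();
  Bsp.fixed = fB.data();
  A.diag.assign(n, 0.0);
  Bsp.diag.assign(n, 0.0);
  auto build_diag = [&](std::vector<double> &diag, NumericVector gx,
                        NumericVector gy, NumericVector gz, NumericVector dd) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = i + j * nx + k * nxy;
          double s = dd[id];
          if (i > 0) s += gx[id - 1];
          if (i < nx - 1) s += gx[id];
          if (j > 0) s += gy[id - nx];
          if (j < ny - 1) s += gy[id];
          if (k > 0) s += gz[id - nxy];
          if (k < nz - 1) s += gz[id];
          diag[id] = s;
        }
  };
  build_diag(A.diag, gxC, gyC, gzC, dCC);
  build_diag(Bsp.diag, gxB, gyB, gzB, dBB);

  // coupling terms vanish when either member of the pair is fixed
  std::vector<double> dCBv(n), dBCv(n);
  for (int i = 0; i < n; ++i) {
    bool off = fC[i] || fB[i];
    dCBv[i] = off ? 0.0 : dCB[i];
    dBCv[i] = off ? 0.0 : dBC[i];
  }

  // 2x2 block-diagonal inverses
  std::vector<double> i00(n), i01(n), i10(n), i11(n);
  for (int id = 0; id < n; ++id) {
    double a = fC[id] ? 1.0 : A.diag[id];
    double dbb = fB[id] ? 1.0 : Bsp.diag[id];
    double det = a * dbb - dCBv[id] * dBCv[id];
    if (std::fabs(det) < 1e-300) det = (det >= 0 ? 1e-300 : -1e-300);
    i00[id] = dbb / det;  i01[id] = -dCBv[id] / det;
    i10[id] = -dBCv[id] / det; i11[id] = a / det;
  }

  std::vector<double> xC(n), xB(n);
  for (int i = 0; i < n; ++i) {
    xC[i] = fC[i] ? 0.0 : x0C[i];
    xB[i] = fB[i] ? 0.0 : x0B[i];
  }

  std::vector<double> rC(n), rB(n), r0C(n), r0B(n), pC(n, 0.0), pB(n, 0.0),
      vC(n, 0.0), vB(n, 0.0), phC(n), phB(n), sC(n), sB(n), shC(n), shB(n),
      tC(n), tB(n), ywC(n), ywB(n);
  apply_block(G, A, Bsp, dCBv.data(), dBCv.data(), xC.data(), xB.data(),
              tC.data(), tB.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    rC[i] = fC[i] ? 0.0 : bC[i] - tC[i];
    rB[i] = fB[i] ? 0.0 : bB[i] - tB[i];
    if (!fC[i]) bnorm += bC[i] * bC[i];
    if (!fB[i]) bnorm += bB[i] * bB[i];
  }
  bnorm = std::sqrt(bnorm);
  double ref = bnorm > 0 ? bnorm : 1.0;
  r0C = rC; r0B = rB;
  double rho = 1.0, alpha = 1.0, omega = 1.0;

  int it = 0;
  double relres = 1.0;
  for (; it < maxit; ++it) {
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += rC[i] * rC[i] + rB[i] * rB[i];
    relres = std::sqrt(rnorm) / ref;
    if (relres <= tol) break;
    double rho1 = 0.0;
    for (int i = 0; i < n; ++i) rho1 += r0C[i] * rC[i] + r0B[i] * rB[i];
    if (std::fabs(rho1) < 1e-300) break;
    double beta = (rho1 / rho) * (alpha / omega);
    for (int i = 0; i < n; ++i) {
      pC[i] = rC[i] + beta * (pC[i] - omega * vC[i]);
      pB[i] = rB[i] + beta * (pB[i] - omega * vB[i]);
    }
    block_ssor(G, A, Bsp, dCBv.data(), dBCv.data(), i00.data(), i01.data(),
               i10.data(), i11.data(), pC.data(), pB.data(), ywC, ywB,
               phC.data(), phB.data());
    apply_block(G, A, Bsp, dCBv.data(), dBCv.data(), phC.data(), phB.data(),
                vC.data(), vB.data());
    double r0v = 0.0;
    for (int i = 0; i < n; ++i) r0v += r0C[i] * vC[i] + r0B[i] * vB[i];
    if (std::fabs(r0v) < 1e-300) break;
    alpha = rho1 / r0v;
    double snorm = 0.0;
    for (int i = 0; i < n; ++i) {
      sC[i] = rC[i] - alpha * vC[i];
      sB[i] = rB[i] - alpha * vB[i];
      snorm += sC[i] * sC[i] + sB[i] * sB[i];
    }
    if (std::sqrt(snorm) / ref <= tol) {
      for (int i = 0; i < n; ++i) {
        xC[i] += alpha * phC[i];
        xB[i] += alpha * phB[i];
      }
      rC = sC; rB = sB;
      relres = std::sqrt(snorm) / ref;
      ++it;
      break;
    }
    block_ssor(G, A, Bsp, dCBv.data(), dBCv.data(), i00.data(), i01.data(),
               i10.data(), i11.data(), sC.data(), sB.data(), ywC, ywB,
               shC.data(), shB.data());
    apply_block(G, A, Bsp, dCBv.data(), dBCv.data(), shC.data(), shB.data(),
                tC.data(), tB.data());
    double ts = 0.0, tt = 0.0;
    for (int i = 0; i < n; ++i) {
      ts += tC[i] * sC[i] + tB[i] * sB[i];
      tt += tC[i] * tC[i] + tB[i] * tB[i];
    }
    if (tt < 1e-300) break;
    omega = ts / tt;
    for (int i = 0; i < n; ++i) {
      xC[i] += alpha * phC[i] + omega * shC[i];
      xB[i] += alpha * phB[i] + omega * shB[i];
      rC[i] = sC[i] - omega * tC[i];
      rB[i] = sB[i] - omega * tB[i];
    }
    rho = rho1;
  }

  NumericVector outC(n), outB(n);
  for (int i = 0; i < n; ++i) {
    outC[i] = fC[i] ? fixvC[i] : xC[i];
    outB[i] = fB[i] ? fixvB[i] : xB[i];
  }
  return List::create(_["C"] = outC, _["B"] = outB, _["iterations"] = it,
                      _["relres"] = relres);
}
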