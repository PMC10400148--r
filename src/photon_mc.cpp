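// Voxel-grid Monte Carlo photon transport with Henyey-Greenstein scattering,
// albedo-weight absorption, Fresnel reflection/refraction at refractive-index
// steps, periodic lateral boundaries, and Russian roulette termination.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: deterministic across platforms.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() {  // in (0, 1]
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

inline void hg_scatter(double *d, double g, Rng &rng) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * rng.uniform() - 1.0;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.uniform());
    ct = (1.0 + g * g - f * f) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * rng.uniform();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.99999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= norm; d[1] /= norm; d[2] /= norm;
}

}  // namespace

// [[Rcpp::export]]
List photon_mc_cpp(IntegerVector labels, IntegerVector dims,
                   NumericVector mua, NumericVector mus, NumericVector g,
                   NumericVector nref, double pitch, int n_photons,
                   double seed, double roulette_threshold = 1e-4) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double hx = pitch;
  NumericVector absorb(n, 0.0);
  double refl = 0.0, trans = 0.0, lost = 0.0;
  Rng rng(static_cast<uint64_t>(seed) * 2685821657736338717ULL + 1ULL);

  const double Lx = nx * hx, Ly = ny * hx;
  const long max_steps = 2000000L;

  for (int ph = 0; ph < n_photons; ++ph) {
    double pos[3] = {rng.uniform() * Lx, rng.uniform() * Ly, 1e-12};
    double dir[3] = {0.0, 0.0, 1.0};
    int v[3] = {(int)(pos[0] / hx), (int)(pos[1] / hx), 0};
    if (v[0] >= nx) v[0] = nx - 1;
    if (v[1] >= ny) v[1] = ny - 1;
    double w = 1.0;
    double tau = -std::log(rng.uniform());
    bool alive = true;
    long steps = 0;

    while (alive) {
      if (++steps > max_steps) { lost += w; break; }
      int idx = v[0] + nx * (v[1] + ny * v[2]);
      int lab = labels[idx];
      double ma = mua[lab], ms = mus[lab];
      double mt = ma + ms;

      // distance to the nearest voxel face along dir
      double tmin = R_PosInf;
      int axis = 0;
      for (int a = 0; a < 3; ++a) {
        double t;
        if (dir[a] > 1e-12) {
          t = ((v[a] + 1) * hx - pos[a]) / dir[a];
        } else if (dir[a] < -1e-12) {
          t = (v[a] * hx - pos[a]) / dir[a];
        } else {
          continue;
        }
        if (t < 0) t = 0;
        if (t < tmin) { tmin = t; axis = a; }
      }

      if (mt > 0 && mt * tmin >= tau) {
        // interaction inside the voxel
        double s = tau / mt;
        pos[0] += dir[0] * s; pos[1] += dir[1] * s; pos[2] += dir[2] * s;
        double da = w * ma / mt;
        absorb[idx] += da;
        w -= da;
        hg_scatter(dir, g[lab], rng);
        if (w < roulette_threshold) {
          if (rng.uniform() < 0.1) w *= 10.0; else { alive = false; break; }
        }
        tau = -std::log(rng.uniform());
        continue;
      }

      // traverse to the face
      tau -= mt * tmin;
      pos[0] += dir[0] * tmin; pos[1] += dir[1] * tmin; pos[2] += dir[2] * tmin;
      int nb[3] = {v[0], v[1], v[2]};
      int step = dir[axis] > 0 ? 1 : -1;
      nb[axis] += step;

      // domain exits in z
      if (axis == 2 && nb[2] < 0) { refl += w; break; }
      if (axis == 2 && nb[2] >= nz) { trans += w; break; }
      // periodic lateral wrap
      if (axis < 2) {
        int nn = axis == 0 ? nx : ny;
        double L = axis == 0 ? Lx : Ly;
        if (nb[axis] < 0) { nb[axis] += nn; pos[axis] += L; }
        if (nb[axis] >= nn) { nb[axis] -= nn; pos[axis] -= L; }
      }

      int nidx = nb[0] + nx * (nb[1] + ny * nb[2]);
      double n1 = nref[lab], n2 = nref[labels[nidx]];
      if (n1 != n2) {
        double ci = std::fabs(dir[axis]);
        double eta = n1 / n2;
        double st2 = eta * eta * (1.0 - ci * ci);
        double R;
        double ct = 0.0;
        if (st2 >= 1.0) {
          R = 1.0;  // total internal reflection
        } else {
          ct = std::sqrt(1.0 - st2);
          double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
          double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
          R = 0.5 * (rs * rs + rp * rp);
        }
        if (rng.uniform() < R) {
          dir[axis] = -dir[axis];
          continue;  // stay in current voxel
        }
        // refract: scale tangential components, set normal component
        for (int a = 0; a < 3; ++a)
          if (a != axis) dir[a] *= eta;
        dir[axis] = (dir[axis] > 0 ? 1.0 : -1.0) * ct;
        double norm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                dir[2] * dir[2]);
        dir[0] /= norm; dir[1] /= norm; dir[2] /= norm;
      }
      v[0] = nb[0]; v[1] = nb[1]; v[2] = nb[2];
    }
  }

  double total_abs = 0.0;
  for (int i = 0; i < n; ++i) total_abs += absorb[i];
  double inv = 1.0 / n_photons;
  for (int i = 0; i < n; ++i) absorb[i] *= inv;
  return List::create(
      _["frac_absorbed"] = absorb,
      _["R"] = refl * inv,
      _["T"] = trans * inv,
      _["A"] = total_abs * inv,
      _["lost"] = lost * inv);
}
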