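#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Voxel Monte Carlo photon transport with weighted absorption deposition,
// Henyey-Greenstein scattering, and Russian roulette below weight 1e-4.
// Photons crossing any face of the grid escape (matched boundary); with
// fresnel = true, top/bottom crossings undergo specular Fresnel reflection
// against an outside index of 1.0. Distances in cm.
//
// Launch: an x-y factorizable beam entering the top face. Entry points are
// uniform over a fiber-diameter square centered at (beam_cx, beam_cy);
// divergence tilts in the x-z and y-z planes are independent and uniform
// within +/- div_half_rad; the mean direction makes incidence_rad with the
// inward normal (tilted in the x-z plane).
//
// Returns per-voxel deposited weight and interaction counts plus the global
// energy ledger: launched = absorbed + escaped + roulette_net, where
// roulette_net is killed weight minus the weight gained by surviving boosts
// (Russian roulette is unbiased only in expectation; the ledger makes the
// per-run balance exact).

static inline void hg_scatter(double &ux, double &uy, double &uz, double g,
                              std::mt19937_64 &rng,
                              std::uniform_real_distribution<double> &U) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * U(rng) - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * U(rng));
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * U(rng);
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// [[Rcpp::export]]
List cpp_mc(IntegerVector dims, NumericVector mua, NumericVector mus,
            NumericVector gvec, NumericVector nvec, double voxel_cm,
            double beam_cx, double beam_cy, double fiber_diam_cm,
            double div_half_rad, double incidence_rad, int n_photons,
            int seed, bool fresnel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double lx = nx * voxel_cm, ly = ny * voxel_cm, lz = nz * voxel_cm;
  const long nvox = (long)nx * ny * nz;
  std::vector<double> dep(nvox, 0.0), hits(nvox, 0.0);
  double absorbed = 0.0, escaped = 0.0, roulette_net = 0.0;
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double w_min = 1e-4, p_survive = 0.1;
  const double si = std::sin(incidence_rad), ci = std::cos(incidence_rad);

  for (int p = 0; p < n_photons; ++p) {
    double x = beam_cx + (U(rng) - 0.5) * fiber_diam_cm;
    double y = beam_cy + (U(rng) - 0.5) * fiber_diam_cm;
    double z = 1e-9;
    double ax = (U(rng) - 0.5) * 2.0 * div_half_rad;
    double ay = (U(rng) - 0.5) * 2.0 * div_half_rad;
    double dx0 = std::tan(ax), dy0 = std::tan(ay), dz0 = 1.0;
    double nrm = std::sqrt(dx0 * dx0 + dy0 * dy0 + dz0 * dz0);
    dx0 /= nrm; dy0 /= nrm; dz0 /= nrm;
    // tilt mean direction by the incidence angle in the x-z plane
    double ux = dz0 * si + dx0 * ci;
    double uy = dy0;
    double uz = dz0 * ci - dx0 * si;
    double w = 1.0;

    for (;;) {
      int ix = (int)std::floor(x / voxel_cm);
      int iy = (int)std::floor(y / voxel_cm);
      int iz = (int)std::floor(z / voxel_cm);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        if (fresnel && (z <= 0.0 || z >= lz) && x >= 0 && x < lx &&
            y >= 0 && y < ly) {
          // specular Fresnel reflection at top/bottom against n_out = 1
          int bz = (z <= 0.0) ? 0 : nz - 1;
          int bix = std::min(std::max(ix, 0), nx - 1);
          int biy = std::min(std::max(iy, 0), ny - 1);
          long bv = bix + (long)nx * (biy + (long)ny * bz);
          double ni = nvec[bv], no = 1.0;
          double cti = std::fabs(uz);
          double sti = std::sqrt(std::max(0.0, 1.0 - cti * cti));
          double stt = ni / no * sti;
          double R;
          if (stt >= 1.0) {
            R = 1.0;                       // total internal reflection
          } else {
            double ctt = std::sqrt(1.0 - stt * stt);
            double rs = (ni * cti - no * ctt) / (ni * cti + no * ctt);
            double rp = (ni * ctt - no * cti) / (ni * ctt + no * cti);
            R = 0.5 * (rs * rs + rp * rp);
          }
          if (U(rng) < R) {
            uz = -uz;
            z = (z <= 0.0) ? -z + 2e-9 : 2.0 * lz - z - 2e-9;
            continue;
          }
        }
        escaped += w;
        break;
      }
      long v = ix + (long)nx * (iy + (long)ny * iz);
      double ma = mua[v], ms = mus[v], mt = ma + ms;
      if (mt <= 0.0) {
        // transparent voxel: fly straight out of the grid
        x += ux * (lx + ly + lz);
        y += uy * (lx + ly + lz);
        z += uz * (lx + ly + lz);
        continue;
      }
      double s = -std::log(U(rng)) / mt;
      x += ux * s; y += uy * s; z += uz * s;
      ix = (int)std::floor(x / voxel_cm);
      iy = (int)std::floor(y / voxel_cm);
      iz = (int)std::floor(z / voxel_cm);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        if (fresnel && (z <= 0.0 || z >= lz) && x >= 0 && x < lx &&
            y >= 0 && y < ly) {
          int bz = (z <= 0.0) ? 0 : nz - 1;
          int bix = std::min(std::max(ix, 0), nx - 1);
          int biy = std::min(std::max(iy, 0), ny - 1);
          long bv = bix + (long)nx * (biy + (long)ny * bz);
          double ni = nvec[bv], no = 1.0;
          double cti = std::fabs(uz);
          double sti = std::sqrt(std::max(0.0, 1.0 - cti * cti));
          double stt = ni / no * sti;
          double R;
          if (stt >= 1.0) R = 1.0;
          else {
            double ctt = std::sqrt(1.0 - stt * stt);
            double rs = (ni * cti - no * ctt) / (ni * cti + no * ctt);
            double rp = (ni * ctt - no * cti) / (ni * ctt + no * cti);
            R = 0.5 * (rs * rs + rp * rp);
          }
          if (U(rng) < R) {
            uz = -uz;
            z = (z <= 0.0) ? -z + 2e-9 : 2.0 * lz - z - 2e-9;
            continue;
          }
        }
        escaped += w;
        break;
      }
      v = ix + (long)nx * (iy + (long)ny * iz);
      ma = mua[v]; ms = mus[v]; mt = ma + ms;
      if (mt <= 0.0) continue;
      double dw = w * ma / mt;
      dep[v] += dw;
      hits[v] += 1.0;
      absorbed += dw;
      w -= dw;
      if (ms > 0.0) hg_scatter(ux, uy, uz, gvec[v], rng, U);
      if (w < w_min) {
        if (U(rng) < p_survive) {
          roulette_net -= w * (1.0 / p_survive - 1.0);
          w /= p_survive;
        } else {
          roulette_net += w;
          break;
        }
      }
    }
  }

  NumericVector fluence(nvox), hits_out(nvox);
  for (long v = 0; v < nvox; ++v) {
    double ma = mua[v];
    fluence[v] = (ma > 0.0)
        ? dep[v] / (ma * voxel_cm * voxel_cm * voxel_cm * n_photons)
        : 0.0;
    hits_out[v] = hits[v];
  }
  fluence.attr("dim") = dims;
  hits_out.attr("dim") = dims;
  return List::create(_["fluence"] = fluence, _["hits"] = hits_out,
                      _["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["roulette_net"] = roulette_net,
                      _["launched"] = (double)n_photons);
}
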