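#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-way delay-and-sum for photoacoustic channel data.
// traces: [element, sample]; grid_x/grid_z: pixel centers in mm.
// fnum <= 0 means full aperture; apod 0 = rectangular, 1 = Hann.
// [[Rcpp::export]]
List cpp_das_pa(NumericMatrix traces, NumericVector elem_x, double fs_hz,
                double t0_s, double c_mps, NumericVector grid_x,
                NumericVector grid_z, double fnum, int apod) {
  const int ne = traces.nrow(), nt = traces.ncol();
  const int nx = grid_x.size(), nz = grid_z.size();
  NumericMatrix img(nz, nx);
  long oob = 0;
  NumericMatrix tt(traces);   // column-major [ne, nt]
  for (int ix = 0; ix < nx; ++ix) {
    double px = grid_x[ix];
    for (int iz = 0; iz < nz; ++iz) {
      double pz = grid_z[iz];
      double half_ap = (fnum > 0.0) ? pz / (2.0 * fnum) : 1e9;
      double acc = 0.0;
      for (int e = 0; e < ne; ++e) {
        double dx = px - elem_x[e];
        double ad = std::fabs(dx);
        if (ad > half_ap) continue;
        double w = (apod == 1) ? 0.5 + 0.5 * std::cos(M_PI * ad / half_ap)
                               : 1.0;
        double r = std::sqrt(dx * dx + pz * pz);
        double idx = (r * 1e-3 / c_mps - t0_s) * fs_hz;
        if (idx < 0.0 || idx > nt - 1) { ++oob; continue; }
        int i = (int)idx;
        double f = idx - i;
        double v = (i >= nt - 1) ? tt(e, nt - 1)
                                 : (1.0 - f) * tt(e, i) + f * tt(e, i + 1);
        acc += w * v;
      }
      img(iz, ix) = acc;
    }
  }
  return List::create(_["image"] = img, _["n_out_of_range"] = (double)oob);
}

// Two-way delay-and-sum for steered line-beam transmits; the transmit delay
// uses the same virtual-source-at-focus model as the forward simulator.
// traces: [line, element, sample] flattened column-major.
// [[Rcpp::export]]
List cpp_das_us(NumericVector traces, NumericVector elem_x,
                NumericVector line_x, double angle_rad, double focal_mm,
                double fs_hz, double t0_s, double c_mps,
                NumericVector grid_x, NumericVector grid_z, double fnum,
                int apod, double line_halfwidth_mm) {
  IntegerVector dims = traces.attr("dim");
  const int nl = dims[0], ne = dims[1], nt = dims[2];
  const int nx = grid_x.size(), nz = grid_z.size();
  NumericMatrix img(nz, nx);
  long oob = 0;
  const double sa = std::sin(angle_rad), ca = std::cos(angle_rad);
  for (int ix = 0; ix < nx; ++ix) {
    double px = grid_x[ix];
    for (int iz = 0; iz < nz; ++iz) {
      double pz = grid_z[iz];
      double half_ap = (fnum > 0.0) ? pz / (2.0 * fnum) : 1e9;
      double acc = 0.0;
      for (int l = 0; l < nl; ++l) {
        double dx = px - line_x[l];
        double dperp = dx * ca - pz * sa;
        double ad_l = std::fabs(dperp);
        if (ad_l > line_halfwidth_mm) continue;
        double wl = 0.5 + 0.5 * std::cos(M_PI * ad_l / line_halfwidth_mm);
        double fx = line_x[l] + focal_mm * sa;
        double fz = focal_mm * ca;
        double u = dx * sa + pz * ca;
        double df = std::sqrt((px - fx) * (px - fx) + (pz - fz) * (pz - fz));
        double sgn = (u >= focal_mm) ? 1.0 : -1.0;
        double t_tx = (focal_mm + sgn * df) * 1e-3 / c_mps;
        for (int e = 0; e < ne; ++e) {
          double ex = px - elem_x[e];
          double ad = std::fabs(ex);
          if (ad > half_ap) continue;
          double w = (apod == 1) ? 0.5 + 0.5 * std::cos(M_PI * ad / half_ap)
                                 : 1.0;
          double r_rx = std::sqrt(ex * ex + pz * pz);
          double idx = ((t_tx + r_rx * 1e-3 / c_mps) - t0_s) * fs_hz;
          if (idx < 0.0 || idx > nt - 1) { ++oob; continue; }
          int i = (int)idx;
          double f = idx - i;
          double v0 = traces[l + nl * (e + ne * i)];
          double v = v0;
          if (i < nt - 1) {
            double v1 = traces[l + nl * (e + ne * (i + 1))];
            v = (1.0 - f) * v0 + f * v1;
          }
          acc += wl * w * v;
        }
      }
      img(iz, ix) = acc;
    }
  }
  return List::create(_["image"] = img, _["n_out_of_range"] = (double)oob);
}
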