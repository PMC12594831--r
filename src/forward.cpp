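#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Band-limited transducer impulse: Gaussian-enveloped cosine at f0 with
// envelope sigma_t chosen by the caller so the -6 dB two-sided amplitude
// spectral width equals the fractional bandwidth times f0.

// Photoacoustic one-way forward model. Distances in mm, times in s.
// Each source voxel radiates a spherical wave p0/r; each element receives it
// through a hard +/-45 degree acceptance cone and the band-limited impulse.
// [[Rcpp::export]]
NumericMatrix cpp_pa_forward(NumericVector src_x, NumericVector src_z,
                             NumericVector src_p0, NumericVector elem_x,
                             double fs_hz, int n_samples, double c_mps,
                             double f0_hz, double sigma_t, double t0_s,
                             double min_r_mm) {
  const int ns = src_x.size(), ne = elem_x.size();
  NumericMatrix out(ne, n_samples);
  const double half_support = 4.0 * sigma_t;
  const double two_pi = 2.0 * M_PI;
  for (int e = 0; e < ne; ++e) {
    for (int s = 0; s < ns; ++s) {
      double dx = src_x[s] - elem_x[e];
      double z = src_z[s];
      if (std::fabs(dx) > z) continue;                 // directivity cone
      double r = std::sqrt(dx * dx + z * z);
      double rr = std::max(r, min_r_mm);
      double tau = r * 1e-3 / c_mps - t0_s;            // arrival time
      double a = src_p0[s] / rr;
      int i0 = (int)std::ceil((tau - half_support) * fs_hz);
      int i1 = (int)std::floor((tau + half_support) * fs_hz);
      if (i0 < 0) i0 = 0;
      if (i1 > n_samples - 1) i1 = n_samples - 1;
      for (int i = i0; i <= i1; ++i) {
        double tt = i / fs_hz - tau;
        out(e, i) += a * std::cos(two_pi * f0_hz * tt) *
                     std::exp(-tt * tt / (2.0 * sigma_t * sigma_t));
      }
    }
  }
  return out;
}

// Two-way ultrasound forward model for steered, focused line-beam transmits.
// Each transmitted line is a virtual source at its focus: the transmit delay
// to a scatterer is (F + sign(u - F) * |r - r_f|)/c with u the scatterer's
// axial coordinate along the steered beam axis. Lateral transmit profile is
// Gaussian with sigma beam_sigma_mm. Returns traces [line, element, sample].
// [[Rcpp::export]]
NumericVector cpp_us_forward(NumericVector sc_x, NumericVector sc_z,
                             NumericVector sc_amp, NumericVector elem_x,
                             NumericVector line_x, double angle_rad,
                             double focal_mm, double fs_hz, int n_samples,
                             double c_mps, double f0_hz, double sigma_t,
                             double beam_sigma_mm, double min_r_mm) {
  const int ns = sc_x.size(), ne = elem_x.size(), nl = line_x.size();
  NumericVector out(nl * ne * n_samples);
  out.attr("dim") = IntegerVector::create(nl, ne, n_samples);
  const double half_support = 4.0 * sigma_t;
  const double two_pi = 2.0 * M_PI;
  const double sa = std::sin(angle_rad), ca = std::cos(angle_rad);
  for (int l = 0; l < nl; ++l) {
    double fx = line_x[l] + focal_mm * sa;   // focus of this line
    double fz = focal_mm * ca;
    for (int s = 0; s < ns; ++s) {
      double dx = sc_x[s] - line_x[l];
      double z = sc_z[s];
      double u = dx * sa + z * ca;            // along-beam coordinate
      double dperp = dx * ca - z * sa;        // across-beam coordinate
      double w = std::exp(-dperp * dperp / (2.0 * beam_sigma_mm * beam_sigma_mm));
      if (w < 1e-4) continue;
      double df = std::sqrt((sc_x[s] - fx) * (sc_x[s] - fx) +
                            (z - fz) * (z - fz));
      double sgn = (u >= focal_mm) ? 1.0 : -1.0;
      double t_tx = (focal_mm + sgn * df) * 1e-3 / c_mps;
      double d_tx = std::max(std::fabs(u), min_r_mm);
      for (int e = 0; e < ne; ++e) {
        double ex = sc_x[s] - elem_x[e];
        if (std::fabs(ex) > z) continue;      // receive directivity cone
        double r_rx = std::sqrt(ex * ex + z * z);
        double tau = t_tx + r_rx * 1e-3 / c_mps;
        double a = w * sc_amp[s] / (d_tx * std::max(r_rx, min_r_mm));
        int i0 = (int)std::ceil((tau - half_support) * fs_hz);
        int i1 = (int)std::floor((tau + half_support) * fs_hz);
        if (i0 < 0) i0 = 0;
        if (i1 > n_samples - 1) i1 = n_samples - 1;
        for (int i = i0; i <= i1; ++i) {
          double tt = i / fs_hz - tau;
          out[l + nl * (e + ne * i)] += a * std::cos(two_pi * f0_hz * tt) *
              std::exp(-tt * tt / (2.0 * sigma_t * sigma_t));
        }
      }
    }
  }
  return out;
}
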