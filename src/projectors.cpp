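#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deposit retarded source contributions onto channel traces.
// Each source voxel is treated as an equal-volume small sphere of radius
// rv, whose retarded-field kernel is the parabola
//   g_i(t) = p0 * pi/R * (rv^2 - u^2) * c,   u = c t - R,  |u| <= rv,
// the exact contribution of a uniform sphere to the integral
// integral p0 delta(t - R'/c) / R' dV'. The kernel is integrated exactly
// over each sample bin (antiderivative F(u) = pi/R (rv^2 u - u^3/3)), so
// total deposited mass is p0 V / R regardless of sampling. The caller
// differentiates in time and scales by 1/(4 pi c^2).
// [[Rcpp::export]]
NumericMatrix forward_deposit(NumericVector sx, NumericVector sy,
                              NumericVector sz, NumericVector p0V,
                              NumericVector rv, NumericVector ex,
                              NumericVector qdx, NumericVector qw,
                              double fs, int nt, double sos,
                              double dir_coef, bool use_dir) {
  const int ne = ex.size(), ns = sx.size(), nq = qdx.size();
  NumericMatrix g(ne, nt);
  const double dt = 1.0 / fs;
  for (int e = 0; e < ne; ++e) {
    for (int q = 0; q < nq; ++q) {
      const double xe = ex[e] + qdx[q];
      const double w0 = qw[q];
      for (int i = 0; i < ns; ++i) {
        const double dx = sx[i] - xe, dy = sy[i], dz = sz[i];
        const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (R <= 1e-9) continue;
        const double a = rv[i];
        const int k0 = (int)std::floor((R - a) / sos * fs);
        const int k1 = (int)std::floor((R + a) / sos * fs) + 1;
        if (k1 < 0 || k0 + 1 >= nt) continue;  // beyond trace: skipped
        // normalization 0.75/a^3 makes the deposited mass p0 V / R for
        // any kernel radius (the radius only controls smoothing)
        double w = w0 * p0V[i] * 0.75 / (a * a * a * R * dt);
        if (use_dir) {
          const double s = std::fabs(dx) / R;
          const double xarg = dir_coef * s;
          if (xarg > 1e-9) w *= std::sin(xarg) / xarg;
        }
        const int kl = k0 > 0 ? k0 : 0;
        const int kh = (k1 < nt - 1) ? k1 : nt - 1;
        for (int k = kl; k <= kh; ++k) {
          // bin [t_k - dt/2, t_k + dt/2] in u = c t - R, clipped to [-a, a]
          double u1 = sos * ((k - 0.5) * dt) - R;
          double u2 = sos * ((k + 0.5) * dt) - R;
          if (u1 < -a) u1 = -a;
          if (u2 > a) u2 = a;
          if (u2 <= u1) continue;
          const double m = (a * a * (u2 - u1) -
                            (u2 * u2 * u2 - u1 * u1 * u1) / 3.0);
          g(e, k) += w * m;
        }
      }
    }
  }
  return g;
}

// Weighted filtered back-projection onto arbitrary pixel lists.
// df holds the per-element data function p - t dp/dt; each pixel sums the
// interpolated samples with weight R * dOmega / Omega0 (dOmega = cos/R^2,
// Omega0 = per-pixel sum of dOmega) and optional regularized inverse
// directivity.
// [[Rcpp::export]]
NumericVector backproject_cpp(NumericMatrix df, double fs, double sos,
                              NumericVector ex, NumericVector px,
                              NumericVector pz, double dir_coef,
                              bool sir_correct, double sir_floor) {
  const int ne = ex.size(), np = px.size(), nt = df.ncol();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double num = 0.0, den = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double dx = px[i] - ex[e], dz = pz[i];
      const double R = std::sqrt(dx * dx + dz * dz);
      if (R <= 1e-9) continue;
      const double ts = R / sos * fs;
      const int k = (int)std::floor(ts);
      if (k < 0 || k + 1 >= nt) continue;  // arrival beyond trace: skipped
      const double frac = ts - k;
      const double v = df(e, k) * (1.0 - frac) + df(e, k + 1) * frac;
      const double cosv = dz / R;
      const double dOmega = cosv / (R * R);
      double w = dOmega;
      if (sir_correct) {
        const double s = std::fabs(dx) / R;
        const double xarg = dir_coef * s;
        double d = 1.0;
        if (xarg > 1e-9) d = std::sin(xarg) / xarg;
        if (d < sir_floor) d = sir_floor;
        w /= d;
      }
      num += w * v;
      den += dOmega;
    }
    out[i] = (den > 0.0) ? 2.0 * num / den : 0.0;
  }
  return out;
}
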