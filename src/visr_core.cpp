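#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Superpose band-limited echoes from point scatterers onto A-lines.
//
// Each scatterer contributes a Gaussian-enveloped cosine pulse centred at
// its instantaneous round-trip delay, weighted laterally by a Gaussian beam
// profile.  Displacement is supplied per mechanical layer (µm, positive =
// away from the transducer) for every slow-time event.
//
// Units: depths/laterals mm, fs MHz, c m/s, sigma_t µs.
// [[Rcpp::export]]
NumericVector rf_synth_cpp(NumericVector z_mm, NumericVector lat_mm,
                           NumericVector amp, IntegerVector layer,
                           NumericMatrix disp_um, NumericVector line_lat_mm,
                           double fs_mhz, double c_mps, double z0_mm,
                           int n_samples, double f0_mhz, double sigma_t_us,
                           double lat_sigma_mm, double lat_cut_mm) {
  const int n = z_mm.size();
  const int ne = disp_um.ncol();
  const int nl = line_lat_mm.size();
  NumericVector out((R_xlen_t)n_samples * ne * nl);
  const double c_mm_us = c_mps / 1000.0;
  const double t0 = 2.0 * z0_mm / c_mm_us;
  const double dt = 1.0 / fs_mhz;
  const double half = 3.5 * sigma_t_us;

  // oversampled pulse table; linear interpolation keeps the per-sample cost
  // to one lookup instead of exp+cos
  const int os = 16;
  const double step = dt / os;
  const int ntab = (int)std::ceil(2.0 * half / step) + 2;
  std::vector<double> tab(ntab);
  const double inv2st = 1.0 / (2.0 * sigma_t_us * sigma_t_us);
  for (int i = 0; i < ntab; ++i) {
    double u = -half + i * step;
    tab[i] = std::exp(-u * u * inv2st) * std::cos(2.0 * M_PI * f0_mhz * u);
  }

  const double line0 = line_lat_mm[0];
  const double pitch = nl > 1 ? line_lat_mm[1] - line_lat_mm[0] : 1.0;
  const double inv2sl = 1.0 / (2.0 * lat_sigma_mm * lat_sigma_mm);
  double *po = REAL(out);

  for (int i = 0; i < n; ++i) {
    int jlo = (int)std::ceil((lat_mm[i] - lat_cut_mm - line0) / pitch);
    int jhi = (int)std::floor((lat_mm[i] + lat_cut_mm - line0) / pitch);
    if (jlo < 0) jlo = 0;
    if (jhi >= nl) jhi = nl - 1;
    if (jlo > jhi) continue;
    const int li = layer[i];
    for (int j = jlo; j <= jhi; ++j) {
      const double dx = lat_mm[i] - line_lat_mm[j];
      const double w = amp[i] * std::exp(-dx * dx * inv2sl);
      for (int e = 0; e < ne; ++e) {
        const double zc = z_mm[i] + disp_um(li, e) / 1000.0;
        const double tc = 2.0 * zc / c_mm_us;
        int s0 = (int)std::ceil((tc - half - t0) * fs_mhz);
        int s1 = (int)std::floor((tc + half - t0) * fs_mhz);
        if (s0 < 0) s0 = 0;
        if (s1 >= n_samples) s1 = n_samples - 1;
        if (s0 > s1) continue;
        double *col = po + ((R_xlen_t)j * ne + e) * n_samples;
        // table index of sample s0
        double idx = (t0 + s0 * dt - tc + half) / step;
        for (int s = s0; s <= s1; ++s, idx += os) {
          int i0 = (int)idx;
          if (i0 < 0 || i0 + 1 >= ntab) continue;
          double fr = idx - i0;
          col[s] += w * (tab[i0] * (1.0 - fr) + tab[i0 + 1] * fr);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n_samples, ne, nl);
  return out;
}

// natural cubic spline through y at integer abscissae 0..n-1; returns second
// derivatives (Thomas algorithm, h = 1)
static void spline_m(const double *y, int n, double *m) {
  std::vector<double> c(n), d(n);
  m[0] = m[n - 1] = 0.0;
  if (n < 3) return;
  // rows i = 1..n-2: m[i-1] + 4 m[i] + m[i+1] = 6 (y[i+1] - 2 y[i] + y[i-1])
  c[1] = 4.0;
  d[1] = 6.0 * (y[2] - 2.0 * y[1] + y[0]);
  for (int i = 2; i <= n - 2; ++i) {
    double f = 1.0 / c[i - 1];
    c[i] = 4.0 - f;
    d[i] = 6.0 * (y[i + 1] - 2.0 * y[i] + y[i - 1]) - f * d[i - 1];
  }
  for (int i = n - 2; i >= 1; --i)
    m[i] = (d[i] - (i == n - 2 ? 0.0 : m[i + 1])) / c[i];
}

static double spline_eval(const double *y, const double *m, int n, double x) {
  int i = (int)std::floor(x);
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  double a = x - i, b = 1.0 - a;
  return m[i] * b * b * b / 6.0 + m[i + 1] * a * a * a / 6.0 +
         (y[i] - m[i] / 6.0) * b + (y[i + 1] - m[i + 1] / 6.0) * a;
}

// Normalized cross-correlation displacement tracking over a slow-time
// ensemble.  Reference = mean of the first n_ref events.  Subsample peak:
// spline upsampling of the correlation function by `interp`, then parabolic
// vertex refinement.  Displacement in samples (convert to µm in R); positive
// lag = echo arrives later = motion away from the transducer.
// [[Rcpp::export]]
List ncc_track_cpp(NumericVector rf, int n_ref, int kernel, int max_lag,
                   int interp, int step) {
  IntegerVector dim = rf.attr("dim");
  const int ns = dim[0], ne = dim[1], nl = dim[2];
  if (kernel < 2) stop("kernel shorter than 2 samples");
  if (kernel + 2 * max_lag > ns) stop("kernel plus search region longer than A-line");

  std::vector<int> starts;
  for (int s0 = max_lag; s0 + kernel + max_lag <= ns; s0 += step)
    starts.push_back(s0);
  const int nk = (int)starts.size();
  if (nk == 0) stop("kernel longer than A-line");

  NumericVector disp((R_xlen_t)nk * ne * nl), corr((R_xlen_t)nk * ne * nl);
  const double *prf = REAL(rf);
  double *pd = REAL(disp), *pc = REAL(corr);

  const int nlag = 2 * max_lag + 1;
  const int nup = (nlag - 1) * interp + 1;
  std::vector<double> ref(ns), cc(nlag), mm(nlag), up(nup);

  for (int j = 0; j < nl; ++j) {
    const double *line = prf + (R_xlen_t)j * ne * ns;
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      for (int e = 0; e < n_ref; ++e) acc += line[(R_xlen_t)e * ns + s];
      ref[s] = acc / n_ref;
    }
    for (int k = 0; k < nk; ++k) {
      const int s0 = starts[k];
      double rs = 0.0, rs2 = 0.0;
      for (int s = 0; s < kernel; ++s) {
        rs += ref[s0 + s];
        rs2 += ref[s0 + s] * ref[s0 + s];
      }
      const double rmean = rs / kernel;
      const double rvar = rs2 / kernel - rmean * rmean;
      for (int e = 0; e < ne; ++e) {
        const double *y = line + (R_xlen_t)e * ns;
        double *out_d = pd + ((R_xlen_t)j * ne + e) * nk + k;
        double *out_c = pc + ((R_xlen_t)j * ne + e) * nk + k;
        if (rvar <= 0.0) { *out_d = NA_REAL; *out_c = 0.0; continue; }
        bool bad = false;
        for (int l = -max_lag; l <= max_lag; ++l) {
          double ys = 0.0, ys2 = 0.0, xy = 0.0;
          const double *yy = y + s0 + l;
          const double *rr = ref.data() + s0;
          for (int s = 0; s < kernel; ++s) {
            ys += yy[s];
            ys2 += yy[s] * yy[s];
            xy += yy[s] * rr[s];
          }
          const double ymean = ys / kernel;
          const double yvar = ys2 / kernel - ymean * ymean;
          if (yvar <= 0.0) { bad = true; break; }
          cc[l + max_lag] =
              (xy / kernel - rmean * ymean) / std::sqrt(rvar * yvar);
        }
        if (bad) { *out_d = NA_REAL; *out_c = 0.0; continue; }
        // upsample correlation by `interp` with a natural cubic spline
        spline_m(cc.data(), nlag, mm.data());
        int ibest = 0;
        for (int u = 0; u < nup; ++u) {
          up[u] = spline_eval(cc.data(), mm.data(), nlag, (double)u / interp);
          if (up[u] > up[ibest]) ibest = u;
        }
        double lag = (double)ibest / interp - max_lag;
        double peak = up[ibest];
        if (ibest > 0 && ibest < nup - 1) {
          const double den = up[ibest - 1] - 2.0 * up[ibest] + up[ibest + 1];
          if (den < 0) {
            const double delta = 0.5 * (up[ibest - 1] - up[ibest + 1]) / den;
            lag += delta / interp;
            peak -= 0.25 * (up[ibest - 1] - up[ibest + 1]) * delta;
          }
        }
        if (lag > max_lag) lag = max_lag;
        if (lag < -max_lag) lag = -max_lag;
        if (peak > 1.0) peak = 1.0;
        if (peak < -1.0) peak = -1.0;
        *out_d = lag;
        *out_c = peak;
      }
    }
  }

  NumericVector centers(nk);
  for (int k = 0; k < nk; ++k) centers[k] = starts[k] + (kernel - 1) / 2.0;
  disp.attr("dim") = IntegerVector::create(nk, ne, nl);
  corr.attr("dim") = IntegerVector::create(nk, ne, nl);
  return List::create(_["lag"] = disp, _["corr"] = corr,
                      _["center_sample"] = centers);
}
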