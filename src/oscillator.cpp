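// Hot loops of the coupled-oscillator simulator. Uses R's RNG (norm_rand)
// so that set.seed() fully determines the output.
#include <Rcpp.h>
using namespace Rcpp;

// Marsaglia polar normal draws on top of R's unif_rand(): deterministic
// given set.seed() and ~2x faster than the inversion-based norm_rand().
struct FastNorm {
  bool has_spare = false;
  double spare = 0.0;
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// Sum of per-bin carriers with shared-phase mixing. Each band bin gets a
// common random-walk phase on top of 2*pi*f*t; each region adds its own
// random-walk perturbation attenuated by (1 - kappa):
//   x_r(t) = a_r * sum_f cos(eta_r(t) + c_f(t))
//          = a_r * [cos(eta_r) * sum_f cos(c_f) - sin(eta_r) * sum_f sin(c_f)]
// so the per-sample trig cost is independent of the bin count. Returns
// n_samples x n_regions (time fastest) for cache-friendly accumulation.
// The regional perturbation eta is a stationary Ornstein-Uhlenbeck
// process (equilibrium s.d. `phase_noise_sd` radians, autocorrelation
// time `tau` samples), so the pair phase difference is stationary and
// the coupling -> PLV map is smooth and monotone.
// [[Rcpp::export]]
NumericMatrix osc_signal_cpp(int n_reg, int n_samples, double fs,
                             NumericVector bins_hz, NumericVector kappa,
                             NumericVector amp, double phase_noise_sd,
                             double tau, double common_phase_sd) {
  NumericMatrix x(n_samples, n_reg);
  NumericMatrix eta(n_samples, n_reg);
  const double rho = tau > 0.5 ? 1.0 - 1.0 / tau : 0.0;
  const double step = phase_noise_sd * std::sqrt(1.0 - rho * rho);
  RNGScope scope;
  FastNorm rnorm_fast;
  for (int r = 0; r < n_reg; ++r) {
    double run = rnorm_fast() * phase_noise_sd;  // start at equilibrium
    const double att = 1.0 - kappa[r];
    double *col = &eta(0, r);
    for (int t = 0; t < n_samples; ++t) {
      run = rho * run + rnorm_fast() * step;
      col[t] = run * att;
    }
  }
  const int nb = bins_hz.size();
  std::vector<double> sr(n_samples, 0.0), si(n_samples, 0.0);
  for (int b = 0; b < nb; ++b) {
    const double w = 2.0 * M_PI * bins_hz[b] / fs;
    double run = 0.0;
    for (int t = 0; t < n_samples; ++t) {
      run += rnorm_fast() * common_phase_sd;
      const double c = w * t + run;
      sr[t] += std::cos(c);
      si[t] += std::sin(c);
    }
  }
  const double inv_sqrt_nb = 1.0 / std::sqrt((double)nb);
  for (int r = 0; r < n_reg; ++r) {
    const double a = amp[r] * inv_sqrt_nb;
    double *xc = &x(0, r);
    const double *ec = &eta(0, r);
    for (int t = 0; t < n_samples; ++t)
      xc[t] = a * (std::cos(ec[t]) * sr[t] - std::sin(ec[t]) * si[t]);
  }
  return x;
}

// Full-complex random spectrum with symmetric amplitude
// 1/sqrt(min(k, n-k)) (power exponent 1). The inverse FFT of each column
// yields a complex series whose real and imaginary parts are two
// independent real 1/f processes, so one column serves two regions.
// Unpack the inverse FFT of the pair spectra into a samples x n_reg real
// matrix (real part -> region 2j-1, imaginary part -> region 2j) and
// normalise to unit RMS.
// [[Rcpp::export]]
NumericMatrix pink_assemble_cpp(ComplexMatrix X, int n_reg) {
  const int n = X.nrow();
  NumericMatrix out(n, n_reg);
  double ss = 0.0;
  for (int r = 0; r < n_reg; ++r) {
    const int j = r / 2;
    const bool re = (r % 2) == 0;
    double *oc = &out(0, r);
    const Rcomplex *xc = &X(0, j);
    for (int t = 0; t < n; ++t) {
      const double v = re ? xc[t].r : xc[t].i;
      oc[t] = v;
      ss += v * v;
    }
  }
  const double scale = 1.0 / std::sqrt(ss / ((double)n * n_reg));
  for (int r = 0; r < n_reg; ++r)
    for (int t = 0; t < n; ++t) out(t, r) *= scale;
  return out;
}

// [[Rcpp::export]]
ComplexMatrix pink_pair_spectrum_cpp(int n_pairs, int n_samples) {
  ComplexMatrix spec(n_samples, n_pairs);
  RNGScope scope;
  FastNorm rnorm_fast;
  for (int j = 0; j < n_pairs; ++j) {
    for (int k = 1; k < n_samples; ++k) {
      const int kk = k <= n_samples - k ? k : n_samples - k;
      const double a = 1.0 / std::sqrt((double)kk);
      Rcomplex z;
      z.r = rnorm_fast() * a;
      z.i = rnorm_fast() * a;
      spec(k, j) = z;
    }
  }
  return spec;
}
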