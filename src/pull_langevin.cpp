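#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// dU/ds for a sum of Gaussian wells U(s) = -sum_j depth_j exp(-((s-c_j)/w_j)^2/2).
// Empty parameter vectors encode the flat (zero) potential.
static inline double grad_u(double s, const double* depth, const double* width,
                            const double* center, int n_wells) {
  double g = 0.0;
  for (int j = 0; j < n_wells; ++j) {
    double d = (s - center[j]) / width[j];
    g += depth[j] * d / width[j] * std::exp(-0.5 * d * d);
  }
  return g;
}

// Euler-Maruyama integration of the overdamped steered pull
//   gamma dx = [-U'(s) dir + k (a(t) - x)] dt + sqrt(2 gamma kBT) dW,
// with anchor a(t) = a0 + v t dir and s = x . dir. Records t, anchor,
// position and spring force at every step (n_steps + 1 rows). Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List pull_langevin_cpp(int n_steps, double dt, double spring_k,
                       double pull_rate, double drag_gamma, double kbt,
                       NumericVector x_init, NumericVector anchor_init,
                       NumericVector pull_dir, NumericVector depth,
                       NumericVector width, NumericVector center,
                       int n_equil_steps) {
  const int dim = x_init.size();
  const int n_wells = depth.size();
  const double *dp = depth.begin(), *wd = width.begin(), *ct = center.begin();
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> a(anchor_init.begin(), anchor_init.end());
  const double inv_gamma = 1.0 / drag_gamma;
  const double noise_sd = std::sqrt(2.0 * kbt * dt * inv_gamma);

  // pre-pull relaxation with the anchor clamped at its initial position
  for (int step = 0; step < n_equil_steps; ++step) {
    double s = 0.0;
    for (int c = 0; c < dim; ++c) s += x[c] * pull_dir[c];
    double gu = grad_u(s, dp, wd, ct, n_wells);
    for (int c = 0; c < dim; ++c) {
      double f = spring_k * (a[c] - x[c]);
      x[c] += (f - gu * pull_dir[c]) * dt * inv_gamma + noise_sd * norm_rand();
    }
  }

  const int n_rec = n_steps + 1;
  NumericVector times(n_rec);
  NumericMatrix anchor(n_rec, dim), pos(n_rec, dim), force(n_rec, dim);
  for (int i = 0; i < n_rec; ++i) {
    times[i] = i * dt;
    for (int c = 0; c < dim; ++c) {
      anchor(i, c) = a[c];
      pos(i, c) = x[c];
      force(i, c) = spring_k * (a[c] - x[c]);
    }
    if (i == n_steps) break;
    double s = 0.0;
    for (int c = 0; c < dim; ++c) s += x[c] * pull_dir[c];
    double gu = grad_u(s, dp, wd, ct, n_wells);
    for (int c = 0; c < dim; ++c) {
      double f = spring_k * (a[c] - x[c]);
      x[c] += (f - gu * pull_dir[c]) * dt * inv_gamma + noise_sd * norm_rand();
      a[c] = anchor_init[c] + pull_rate * ((i + 1) * dt) * pull_dir[c];
    }
  }
  return List::create(_["time"] = times, _["anchor"] = anchor,
                      _["position"] = pos, _["force"] = force);
}
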