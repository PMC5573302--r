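#include <Rcpp.h>
using namespace Rcpp;

// 26-neighbor (Moore) stencil helpers for the explicit field solver.
// `nb` is an n x 26 matrix of 1-based neighbor indices, 0 where the neighbor
// falls outside the lattice. The no-flux boundary convention replaces a
// missing neighbor by the center value, so it contributes zero to the
// Laplacian.

// [[Rcpp::export]]
NumericVector cpp_nb_sum26(const NumericVector& C, const IntegerMatrix& nb) {
  const int n = C.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ci = C[i];
    double s = 0.0;
    for (int k = 0; k < 26; ++k) {
      const int j = nb(i, k);
      s += (j > 0) ? C[j - 1] : ci;
    }
    out[i] = s;
  }
  return out;
}

// Neighborhood summary statistics over in-bounds Moore neighbors only
// (used by the site-selection rules, where boundary neighborhoods are
// genuinely smaller). sd is the population standard deviation. Sites with
// no neighbors (1x1x1 lattice) report 0/0/0.

// [[Rcpp::export]]
List cpp_nb_stats(const NumericVector& C, const IntegerMatrix& nb) {
  const int n = C.size();
  NumericVector mean(n), sd(n), mx(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, s2 = 0.0, m = R_NegInf;
    int cnt = 0;
    for (int k = 0; k < 26; ++k) {
      const int j = nb(i, k);
      if (j > 0) {
        const double v = C[j - 1];
        s += v;
        s2 += v * v;
        if (v > m) m = v;
        ++cnt;
      }
    }
    if (cnt == 0) {
      mean[i] = 0.0; sd[i] = 0.0; mx[i] = 0.0;
    } else {
      const double mu = s / cnt;
      double var = s2 / cnt - mu * mu;
      if (var < 0) var = 0;  // guard rounding
      mean[i] = mu;
      sd[i] = std::sqrt(var);
      mx[i] = m;
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd, _["max"] = mx);
}

// One explicit sub-step of the reaction-diffusion update:
//   C' = C + lambda * (sum_nb C - 26 C) - a * C + b
// where lambda = D * dt / dS^2 and a, b are per-site linear-removal and
// constant-source coefficients with the sub-step dt already folded in.
// Negative results are clamped to zero; the clamp count is returned so the
// caller can log it.

// [[Rcpp::export]]
List cpp_diffuse_substep(const NumericVector& C, const IntegerMatrix& nb,
                         const double lambda, const NumericVector& a,
                         const NumericVector& b) {
  const int n = C.size();
  NumericVector out(n);
  int clamped = 0;
  for (int i = 0; i < n; ++i) {
    const double ci = C[i];
    double s = 0.0;
    for (int k = 0; k < 26; ++k) {
      const int j = nb(i, k);
      s += (j > 0) ? C[j - 1] : ci;
    }
    double v = ci + lambda * (s - 26.0 * ci) - a[i] * ci + b[i];
    if (v < 0) { v = 0; ++clamped; }
    out[i] = v;
  }
  return List::create(_["C"] = out, _["clamped"] = clamped);
}
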