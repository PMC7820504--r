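#include <Rcpp.h>
using namespace Rcpp;

// State layout: L, H, F, P, Q where Q is the cumulative successful-quit
// flow integral of c(s)L(s) + lam*c(s)H(s) ds from t = 0 (negative for
// t < 0). Parameter vector layout (see .pvec() on the R side):
// 0 mu, 1 zeta, 2 eta, 3 lam, 4 u0, 5 v0, 6 c0, 7 r0, 8 g0,
// 9 delta_u, 10 delta_v, 11 delta_c, 12 delta_r, 13 delta_g.

static inline void rhs(const double t, const double *y, double *dy,
                       const double *p) {
  const double mu = p[0], zeta = p[1], eta = p[2], lam = p[3];
  const double u = p[4] * std::exp(p[9] * t);
  const double v = p[5] * std::exp(p[10] * t);
  const double c = p[6] * std::exp(p[11] * t);
  const double r = p[7] * std::exp(p[12] * t);
  const double g = p[8] * std::exp(-p[13] * t);
  const double L = y[0], H = y[1], F = y[2], P = y[3];
  const double N = P - L - H - F;
  const double quitflow = c * L + lam * c * H;
  dy[0] = u * N + r * F - (v + c + mu) * L;
  dy[1] = v * L - (lam * c + zeta * mu) * H;
  dy[2] = quitflow - (r + eta * mu) * F;
  dy[3] = g * P;
  dy[4] = quitflow;
}

static inline void rk4_step(double t, double h, double *y, const double *p) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  rhs(t, y, k1, p);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(t + 0.5 * h, tmp, k2, p);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(t + 0.5 * h, tmp, k3, p);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(t + h, tmp, k4, p);
  for (int i = 0; i < 5; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// March from t0 to each requested time in `times` (sorted, all on the same
// side of t0), overwriting y in place and storing rows of `out`.
static void march(double t0, const double *y0, const NumericVector &times,
                  const IntegerVector &rows, NumericMatrix &out,
                  const double *p, double hmax) {
  double y[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  double t = t0;
  for (int k = 0; k < times.size(); ++k) {
    const double target = times[k];
    const double span = target - t;
    if (std::abs(span) > 1e-12) {
      const int nstep = (int)std::ceil(std::abs(span) / hmax);
      const double h = span / nstep;
      for (int s = 0; s < nstep; ++s) rk4_step(t + s * h, h, y, p);
    }
    t = target;
    for (int i = 0; i < 5; ++i) out(rows[k], i) = y[i];
  }
}

// [[Rcpp::export(name = ".integrate_states_cpp")]]
NumericMatrix integrate_states_cpp(NumericVector pars, NumericVector init,
                                   NumericVector times, double hmax = 0.025) {
  if (pars.size() != 14) stop("parameter vector must have length 14");
  if (init.size() != 5) stop("initial state must have length 5 (L,H,F,P,Q)");
  if (hmax <= 0) stop("hmax must be positive");
  const int n = times.size();
  NumericMatrix out(n, 5);
  // times may straddle t = 0 (the anchor of the initial condition); march
  // backwards for the negative part and forwards for the rest.
  std::vector<int> fwd, bwd;
  for (int k = 0; k < n; ++k) {
    if (k > 0 && times[k] < times[k - 1]) stop("times must be nondecreasing");
    (times[k] < 0 ? bwd : fwd).push_back(k);
  }
  const double *y0 = REAL(init);
  const double *p = REAL(pars);
  if (!bwd.empty()) {
    std::reverse(bwd.begin(), bwd.end());
    NumericVector tb(bwd.size());
    IntegerVector rb(bwd.size());
    for (size_t k = 0; k < bwd.size(); ++k) {
      tb[k] = times[bwd[k]];
      rb[k] = bwd[k];
    }
    march(0.0, y0, tb, rb, out, p, hmax);
  }
  if (!fwd.empty()) {
    NumericVector tf(fwd.size());
    IntegerVector rf(fwd.size());
    for (size_t k = 0; k < fwd.size(); ++k) {
      tf[k] = times[fwd[k]];
      rf[k] = fwd[k];
    }
    march(0.0, y0, tf, rf, out, p, hmax);
  }
  colnames(out) = CharacterVector::create("L", "H", "F", "P", "Q");
  return out;
}
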