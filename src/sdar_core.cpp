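#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential discounted AR recursion.
//
// Given a (zero-mean) series x, model order p and discounting rate r, the
// recursion maintains the discounted least-squares AR coefficient estimate
// A_t, its gain matrix V_t (a Sherman-Morrison style inverse of the
// discounted Gram matrix), the auxiliary moment vector M_t, the one-step
// predictive mean mu_t and the exponentially weighted residual variance
// sigma2_t.  The per-sample detection statistic is the quadratic loss
// psi_t = (x_t - mu_t)^2.
//
// Initialization at t = p (1-based): V = I_p, M = A0 (Burg fit of a
// training segment), sigma2 = s20, A = V M; the lag buffer holds
// (x_p, ..., x_1).  Samples t <= p get psi = 0 and carry the initial
// parameter values in the returned traces.
//
// V is re-symmetrized each step; sigma2 is floored at 1e-12 so a constant
// segment cannot collapse the model variance to exactly zero.

// [[Rcpp::export(name = ".sdar_filter_cpp")]]
List sdar_filter_cpp(NumericVector x, int p, double r,
                     NumericVector A0, double s20) {
  const int n = x.size();
  if (p < 1) stop("model order p must be >= 1");
  if (!(r > 0.0 && r < 1.0)) stop("discounting rate r must be in (0, 1)");
  if (n <= p) stop("signal shorter than the model order");
  if (A0.size() != p) stop("initial coefficient vector has wrong length");

  NumericVector psi(n), mu(n), sig2(n);
  NumericMatrix Atrace(n, p);
  std::vector<double> M(p), A(p), xb(p), Vx(p);
  std::vector<double> V((size_t)p * p, 0.0);

  for (int i = 0; i < p; ++i) {
    V[(size_t)i * p + i] = 1.0;       // V = I_p
    M[i] = A0[i];
    A[i] = A0[i];                     // A = V M with V = I
    xb[i] = x[p - 1 - i];             // newest first: (x_p, ..., x_1)
  }
  double sigma2 = s20;
  double max_asym = 0.0;

  for (int t = 0; t < p; ++t) {       // t (0-based) < p: before init point
    psi[t] = 0.0; mu[t] = 0.0; sig2[t] = s20;
    for (int i = 0; i < p; ++i) Atrace(t, i) = A0[i];
  }

  const double omr = 1.0 - r;
  for (int t = p; t < n; ++t) {       // 0-based t corresponds to sample t+1
    const double xt = x[t];
    if (!std::isfinite(xt)) stop("non-finite sample at index %d", t + 1);

    // c_t = r * xb' V xb,  Vx = V xb
    double c = 0.0;
    for (int i = 0; i < p; ++i) {
      double acc = 0.0;
      for (int j = 0; j < p; ++j) acc += V[(size_t)i * p + j] * xb[j];
      Vx[i] = acc;
      c += xb[i] * acc;
    }
    c *= r;

    const double denom = omr + c;
    if (denom <= 0.0 || !std::isfinite(denom))
      stop("degenerate gain: 1 - r + c_t underflowed at sample %d", t + 1);

    // M_t = (1-r) M + r * xb * x_t
    for (int i = 0; i < p; ++i) M[i] = omr * M[i] + r * xb[i] * xt;

    // V_t = ( V - (r/(1-r+c)) Vx Vx' ) / (1-r), then symmetrize
    const double g = r / denom;
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        V[(size_t)i * p + j] = (V[(size_t)i * p + j] - g * Vx[i] * Vx[j]) / omr;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        const double a = V[(size_t)i * p + j], b = V[(size_t)j * p + i];
        const double d = std::fabs(a - b);
        if (d > max_asym) max_asym = d;
        const double s = 0.5 * (a + b);
        V[(size_t)i * p + j] = s;
        V[(size_t)j * p + i] = s;
      }

    // A_t = V_t M_t;  mu_t = A_t' xb
    double m = 0.0;
    for (int i = 0; i < p; ++i) {
      double acc = 0.0;
      for (int j = 0; j < p; ++j) acc += V[(size_t)i * p + j] * M[j];
      A[i] = acc;
      m += acc * xb[i];
    }

    const double e = xt - m;
    sigma2 = omr * sigma2 + r * e * e;
    if (sigma2 < 1e-12) sigma2 = 1e-12;

    mu[t] = m;
    sig2[t] = sigma2;
    psi[t] = e * e;
    for (int i = 0; i < p; ++i) Atrace(t, i) = A[i];

    // push x_t into the lag buffer (newest first)
    for (int i = p - 1; i > 0; --i) xb[i] = xb[i - 1];
    xb[0] = xt;
  }

  NumericMatrix Vout(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) Vout(i, j) = V[(size_t)i * p + j];

  return List::create(_["psi"] = psi, _["mu"] = mu, _["sigma2"] = sig2,
                      _["coefficients"] = Atrace, _["V"] = Vout,
                      _["max_asymmetry"] = max_asym);
}
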