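// EM loop for bivariate Gaussian mixtures under the eight
// eigen-decomposition covariance families with closed-form M-steps.
// Everything is 2-D, so covariances are carried as (s11, s22, s12)
// triples and all linear algebra is explicit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Family codes: 0 EII, 1 VII, 2 EEI, 3 VEI, 4 EVI, 5 VVI, 6 EEE, 7 VVV
static int model_code(const std::string &m) {
  if (m == "EII") return 0;
  if (m == "VII") return 1;
  if (m == "EEI") return 2;
  if (m == "VEI") return 3;
  if (m == "EVI") return 4;
  if (m == "VVI") return 5;
  if (m == "EEE") return 6;
  if (m == "VVV") return 7;
  return -1;
}

// [[Rcpp::export(name = ".em_loop_cpp")]]
List em_loop_cpp(NumericMatrix X, NumericMatrix resp0, std::string model,
                 double tol, int max_iter, NumericVector vfloor,
                 double min_count) {
  const int n = X.nrow();
  const int K = resp0.ncol();
  const int mc = model_code(model);
  if (mc < 0) stop("unsupported covariance model: %s", model);

  const double *x1 = &X(0, 0);
  const double *x2 = &X(0, 1);

  std::vector<double> resp(resp0.begin(), resp0.end()); // column-major
  std::vector<double> pro(K), mu1(K), mu2(K);
  std::vector<double> s11(K), s22(K), s12(K);
  std::vector<double> w11(K), w22(K), w12(K), nk(K);
  std::vector<double> logd(n * K);
  std::vector<double> trace;
  trace.reserve(64);

  double ll_old = R_NegInf;
  bool decreased = false;
  std::string fail = "";
  int iters = 0;

  for (int iter = 1; iter <= max_iter; ++iter) {
    // ---- M step ----
    for (int k = 0; k < K; ++k) {
      const double *r = &resp[(size_t)k * n];
      double sk = 0.0, m1 = 0.0, m2 = 0.0;
      for (int i = 0; i < n; ++i) {
        sk += r[i];
        m1 += r[i] * x1[i];
        m2 += r[i] * x2[i];
      }
      if (sk < min_count) { fail = "component weight collapsed"; break; }
      nk[k] = sk;
      mu1[k] = m1 / sk;
      mu2[k] = m2 / sk;
      double a = 0.0, b = 0.0, c = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d1 = x1[i] - mu1[k];
        const double d2 = x2[i] - mu2[k];
        a += r[i] * d1 * d1;
        b += r[i] * d2 * d2;
        c += r[i] * d1 * d2;
      }
      w11[k] = a; w22[k] = b; w12[k] = c;
      pro[k] = sk / n;
    }
    if (!fail.empty()) break;

    switch (mc) {
    case 0: { // EII: lambda I shared
      double tr = 0.0;
      for (int k = 0; k < K; ++k) tr += w11[k] + w22[k];
      const double lam = tr / (2.0 * n);
      for (int k = 0; k < K; ++k) { s11[k] = s22[k] = lam; s12[k] = 0.0; }
      break;
    }
    case 1: { // VII: lambda_k I
      for (int k = 0; k < K; ++k) {
        const double lam = (w11[k] + w22[k]) / (2.0 * nk[k]);
        s11[k] = s22[k] = lam; s12[k] = 0.0;
      }
      break;
    }
    case 2: { // EEI: shared diagonal
      double a = 0.0, b = 0.0;
      for (int k = 0; k < K; ++k) { a += w11[k]; b += w22[k]; }
      for (int k = 0; k < K; ++k) {
        s11[k] = a / n; s22[k] = b / n; s12[k] = 0.0;
      }
      break;
    }
    case 3: { // VEI: lambda_k B, B diagonal det 1 (short fixed point)
      std::vector<double> lam(K);
      for (int k = 0; k < K; ++k) lam[k] = (w11[k] + w22[k]) / (2.0 * nk[k]);
      double b1 = 1.0, b2 = 1.0;
      for (int it = 0; it < 20; ++it) {
        double r1 = 0.0, r2 = 0.0;
        for (int k = 0; k < K; ++k) {
          r1 += w11[k] / lam[k];
          r2 += w22[k] / lam[k];
        }
        if (r1 <= 0.0 || r2 <= 0.0) { fail = "VEI shape degenerate"; break; }
        const double g = std::sqrt(r1 * r2); // normalize to unit determinant
        const double n1 = r1 / g;
        const double n2 = r2 / g;
        for (int k = 0; k < K; ++k)
          lam[k] = (w11[k] / n1 + w22[k] / n2) / (2.0 * nk[k]);
        const double diff = std::fabs(n1 - b1) + std::fabs(n2 - b2);
        b1 = n1; b2 = n2;
        if (diff < 1e-12) break;
      }
      if (!fail.empty()) break;
      for (int k = 0; k < K; ++k) {
        s11[k] = lam[k] * b1; s22[k] = lam[k] * b2; s12[k] = 0.0;
      }
      break;
    }
    case 4: { // EVI: lambda A_k, A_k diagonal det 1
      double lam = 0.0;
      bool bad = false;
      for (int k = 0; k < K; ++k) {
        const double det = w11[k] * w22[k];
        if (det <= 0.0) { bad = true; break; }
        lam += std::sqrt(det);
      }
      if (bad) { fail = "EVI shape degenerate"; break; }
      lam /= n;
      for (int k = 0; k < K; ++k) {
        const double sd = std::sqrt(w11[k] * w22[k]);
        s11[k] = lam * w11[k] / sd;
        s22[k] = lam * w22[k] / sd;
        s12[k] = 0.0;
      }
      break;
    }
    case 5: { // VVI
      for (int k = 0; k < K; ++k) {
        s11[k] = w11[k] / nk[k]; s22[k] = w22[k] / nk[k]; s12[k] = 0.0;
      }
      break;
    }
    case 6: { // EEE
      double a = 0.0, b = 0.0, c = 0.0;
      for (int k = 0; k < K; ++k) { a += w11[k]; b += w22[k]; c += w12[k]; }
      for (int k = 0; k < K; ++k) {
        s11[k] = a / n; s22[k] = b / n; s12[k] = c / n;
      }
      break;
    }
    case 7: { // VVV
      for (int k = 0; k < K; ++k) {
        s11[k] = w11[k] / nk[k]; s22[k] = w22[k] / nk[k];
        s12[k] = w12[k] / nk[k];
      }
      break;
    }
    }
    if (!fail.empty()) break;

    for (int k = 0; k < K; ++k) {
      if (s11[k] < vfloor[0] || s22[k] < vfloor[1]) {
        fail = "component variance below floor";
        break;
      }
      if (s11[k] * s22[k] - s12[k] * s12[k] <= 0.0) {
        fail = "singular component covariance";
        break;
      }
    }
    if (!fail.empty()) break;

    // ---- E step ----
    for (int k = 0; k < K; ++k) {
      const double det = s11[k] * s22[k] - s12[k] * s12[k];
      const double cst = std::log(pro[k]) - LOG2PI - 0.5 * std::log(det);
      const double i11 = s22[k] / det, i22 = s11[k] / det,
                   i12 = -s12[k] / det;
      double *L = &logd[(size_t)k * n];
      for (int i = 0; i < n; ++i) {
        const double d1 = x1[i] - mu1[k];
        const double d2 = x2[i] - mu2[k];
        L[i] = cst - 0.5 * (d1 * d1 * i11 + 2.0 * d1 * d2 * i12 +
                            d2 * d2 * i22);
      }
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = logd[i];
      for (int k = 1; k < K; ++k) {
        const double v = logd[(size_t)k * n + i];
        if (v > m) m = v;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += std::exp(logd[(size_t)k * n + i] - m);
      const double lse = m + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[(size_t)k * n + i] = std::exp(logd[(size_t)k * n + i] - lse);
    }
    if (!std::isfinite(ll)) { fail = "non-finite log-likelihood"; break; }
    trace.push_back(ll);
    iters = iter;
    if (ll < ll_old - 1e-8 * (std::fabs(ll_old) + 1.0)) decreased = true;
    const bool done = std::isfinite(ll_old) &&
      std::fabs(ll - ll_old) <= tol * (std::fabs(ll) + 1e-3);
    ll_old = ll;
    if (done) break;
  }

  if (!fail.empty() || iters == 0)
    return List::create(_["ok"] = false,
                        _["reason"] = fail.empty() ? "no iterations" : fail);

  NumericMatrix mean(2, K);
  NumericVector sigma(Dimension(2, 2, K));
  NumericVector pro_out(K);
  for (int k = 0; k < K; ++k) {
    mean(0, k) = mu1[k];
    mean(1, k) = mu2[k];
    pro_out[k] = pro[k];
    sigma[4 * k + 0] = s11[k];
    sigma[4 * k + 3] = s22[k];
    sigma[4 * k + 1] = s12[k];
    sigma[4 * k + 2] = s12[k];
  }
  NumericMatrix resp_out(n, K);
  std::copy(resp.begin(), resp.end(), resp_out.begin());
  return List::create(_["ok"] = true, _["loglik"] = ll_old,
                      _["pro"] = pro_out, _["mean"] = mean,
                      _["sigma"] = sigma, _["resp"] = resp_out,
                      _["iterations"] = iters,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["decreased"] = decreased);
}
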