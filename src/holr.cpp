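#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// logistic cdf / pdf, numerically safe in both tails
static inline double F(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}
static inline double f(double x) {
  double p = F(x);
  return p * (1.0 - p);
}
// d f(x) / dx = f(x) (1 - 2 F(x))
static inline double fp(double x) {
  double p = F(x);
  return p * (1.0 - p) * (1.0 - 2.0 * p);
}

// log P(Y = y | eta shift s) with cutpoints zeta, plus d/ds and d2/ds2 of the
// log-prob, where the category prob is F(zeta_y - s) - F(zeta_{y-1} - s)
// (s = x'beta + u). Boundaries use F(+inf)=1, F(-inf)=0.
struct LP { double lp, d1, d2, dza, dzb; };

// log P(Y = y) for linear predictor shift s (= x'beta + u), with derivatives:
// d1 = d/ds, d2 = d2/ds2, dza = d/d zeta_y (upper cutpoint),
// dzb = d/d zeta_{y-1} (lower cutpoint)
static inline LP logprob(int y, int K, const double* zeta, double s) {
  double Fa, fa, fpa, Fb, fb, fpb;
  if (y < K - 1) {
    double a = zeta[y] - s;
    Fa = F(a); fa = f(a); fpa = fp(a);
  } else { Fa = 1.0; fa = 0.0; fpa = 0.0; }
  if (y > 0) {
    double b = zeta[y - 1] - s;
    Fb = F(b); fb = f(b); fpb = fp(b);
  } else { Fb = 0.0; fb = 0.0; fpb = 0.0; }
  double P = Fa - Fb;
  if (P < 1e-300) P = 1e-300;
  // dP/ds = -fa + fb ; d2P/ds2 = fpa - fpb
  double d1 = (fb - fa) / P;
  double d2 = (fpa - fpb) / P - d1 * d1;
  LP out; out.lp = std::log(P); out.d1 = d1; out.d2 = d2;
  out.dza = fa / P; out.dzb = -fb / P;
  return out;
}

// Marginal log-likelihood of a random-intercept cumulative-logit model.
// Data must be sorted by cluster. cl_start (0-based) / cl_len index persons.
// sigma = random-intercept SD. nodes/weights: Gauss-Hermite rule (physicists'
// convention: int e^{-x^2} g(x) dx ~ sum w_t g(x_t)).
// adaptive: center/scale nodes at the per-cluster posterior mode; otherwise
// plain GH centered at 0 with scale sigma.
// [[Rcpp::export]]
List holr_loglik_cpp(NumericVector zeta, NumericVector beta, double sigma,
                     IntegerVector y, NumericMatrix X,
                     IntegerVector cl_start, IntegerVector cl_len,
                     NumericVector gh_x, NumericVector gh_w,
                     bool adaptive = true) {
  const int n = y.size();
  const int K = zeta.size() + 1;
  const int p = beta.size();
  const int J = cl_start.size();
  const int T = gh_x.size();
  const double* z = zeta.begin();

  // linear predictor m_i = x_i' beta
  std::vector<double> m(n, 0.0);
  for (int q = 0; q < p; ++q) {
    double bq = beta[q];
    if (bq != 0.0)
      for (int i = 0; i < n; ++i) m[i] += X(i, q) * bq;
  }

  NumericVector cl_ll(J), cl_mode(J);
  double total = 0.0;
  bool ok = true;

  if (sigma < 1e-8) {                       // boundary: no integration
    for (int j = 0; j < J; ++j) {
      double s = 0.0;
      for (int i = cl_start[j]; i < cl_start[j] + cl_len[j]; ++i)
        s += logprob(y[i], K, z, m[i]).lp;
      cl_ll[j] = s; cl_mode[j] = 0.0; total += s;
    }
    return List::create(_["loglik"] = total, _["cluster_loglik"] = cl_ll,
                        _["modes"] = cl_mode, _["ok"] = ok);
  }

  const double s2 = sigma * sigma;
  const double lognorm = -0.5 * std::log(2.0 * M_PI * s2);
  std::vector<double> logw(T);
  for (int t = 0; t < T; ++t) logw[t] = std::log(gh_w[t]);

  for (int j = 0; j < J; ++j) {
    const int i0 = cl_start[j], nj = cl_len[j];

    // joint log-density g(u) = sum_i log P_i(u) - u^2/(2 s2) + lognorm
    auto gval = [&](double u, double& g1, double& g2) {
      double g = lognorm - u * u / (2.0 * s2);
      g1 = -u / s2; g2 = -1.0 / s2;
      for (int i = i0; i < i0 + nj; ++i) {
        LP l = logprob(y[i], K, z, m[i] + u);
        g += l.lp; g1 += l.d1; g2 += l.d2;
      }
      return g;
    };

    double uhat = 0.0, g1, g2;
    double g = gval(uhat, g1, g2);
    bool found = false;
    if (adaptive) {
      for (int it = 0; it < 100; ++it) {
        if (!std::isfinite(g) || !std::isfinite(g1) || g2 >= -1e-12) break;
        double step = -g1 / g2;
        if (std::fabs(step) < 1e-11 * (1.0 + std::fabs(uhat))) {
          found = true; break;
        }
        double unew = uhat + step, gn1, gn2;
        double gn = gval(unew, gn1, gn2);
        int half = 0;
        while ((!std::isfinite(gn) || gn < g) && half < 30) {
          step *= 0.5; unew = uhat + step; gn = gval(unew, gn1, gn2); ++half;
        }
        if (gn < g) { found = true; break; }   // cannot improve: at the mode
        uhat = unew; g = gn; g1 = gn1; g2 = gn2;
        if (std::fabs(g1) < 1e-10 * (1.0 + std::fabs(g))) { found = true; break; }
      }
      // iteration cap reached but curvature is usable: quadrature centred at
      // the best point found is still far better than the plain rule
      if (!found && std::isfinite(g) && std::isfinite(g2) && g2 < -1e-10)
        found = true;
    }

    double llj;
    if (adaptive && found && std::isfinite(g2) && g2 < -1e-10) {
      // AGQ: int e^{g(u)} du ~ s * sum_t w_t e^{x_t^2} e^{g(uhat + s x_t)}
      double h = -g2, sc = std::sqrt(2.0 / h);
      double mx = -INFINITY;
      std::vector<double> terms(T);
      for (int t = 0; t < T; ++t) {
        double d1d, d2d;
        terms[t] = logw[t] + gh_x[t] * gh_x[t] +
          gval(uhat + sc * gh_x[t], d1d, d2d);
        if (terms[t] > mx) mx = terms[t];
      }
      double sum = 0.0;
      for (int t = 0; t < T; ++t) sum += std::exp(terms[t] - mx);
      llj = std::log(sc) + mx + std::log(sum);
    } else {
      // plain GH against the N(0, s2) weight
      double mx = -INFINITY;
      std::vector<double> terms(T);
      const double halflogpi = 0.5 * std::log(M_PI);
      for (int t = 0; t < T; ++t) {
        double u = M_SQRT2 * sigma * gh_x[t];
        double s = 0.0;
        for (int i = i0; i < i0 + nj; ++i)
          s += logprob(y[i], K, z, m[i] + u).lp;
        terms[t] = logw[t] - halflogpi + s;
        if (terms[t] > mx) mx = terms[t];
      }
      double sum = 0.0;
      for (int t = 0; t < T; ++t) sum += std::exp(terms[t] - mx);
      llj = mx + std::log(sum);
      uhat = 0.0;
      if (adaptive) ok = false;   // records that the fallback was used
    }
    cl_ll[j] = llj; cl_mode[j] = uhat; total += llj;
  }

  return List::create(_["loglik"] = total, _["cluster_loglik"] = cl_ll,
                      _["modes"] = cl_mode, _["ok"] = ok);
}

// Marginal log-likelihood AND its gradient wrt (zeta, beta, log sigma).
// The gradient is the quadrature-weighted posterior expectation of the
// integrand's score (nodes treated as fixed), accurate to quadrature error.
// [[Rcpp::export]]
List holr_loglik_grad_cpp(NumericVector zeta, NumericVector beta,
                          double sigma, IntegerVector y, NumericMatrix X,
                          IntegerVector cl_start, IntegerVector cl_len,
                          NumericVector gh_x, NumericVector gh_w) {
  const int n = y.size();
  const int K = zeta.size() + 1;
  const int p = beta.size();
  const int J = cl_start.size();
  const int T = gh_x.size();
  const int q = (K - 1) + p + 1;       // zeta, beta, log sigma
  const double* z = zeta.begin();

  std::vector<double> m(n, 0.0);
  for (int r = 0; r < p; ++r) {
    double br = beta[r];
    if (br != 0.0)
      for (int i = 0; i < n; ++i) m[i] += X(i, r) * br;
  }

  NumericVector grad(q);
  double total = 0.0;

  if (sigma < 1e-8) {                  // boundary: plain sum at u = 0
    for (int i = 0; i < n; ++i) {
      LP l = logprob(y[i], K, z, m[i]);
      total += l.lp;
      if (y[i] < K - 1) grad[y[i]] += l.dza;
      if (y[i] > 0)     grad[y[i] - 1] += l.dzb;
      for (int r = 0; r < p; ++r) grad[K - 1 + r] += l.d1 * X(i, r);
    }
    return List::create(_["loglik"] = total, _["grad"] = grad);
  }

  const double s2 = sigma * sigma;
  const double lognorm = -0.5 * std::log(2.0 * M_PI * s2);
  std::vector<double> logw(T);
  for (int t = 0; t < T; ++t) logw[t] = std::log(gh_w[t]);

  std::vector<double> terms(T), gz(K - 1), gb(p);

  for (int j = 0; j < J; ++j) {
    const int i0 = cl_start[j], nj = cl_len[j];

    auto gval = [&](double u, double& g1, double& g2) {
      double g = lognorm - u * u / (2.0 * s2);
      g1 = -u / s2; g2 = -1.0 / s2;
      for (int i = i0; i < i0 + nj; ++i) {
        LP l = logprob(y[i], K, z, m[i] + u);
        g += l.lp; g1 += l.d1; g2 += l.d2;
      }
      return g;
    };

    double uhat = 0.0, g1, g2;
    double g = gval(uhat, g1, g2);
    for (int it = 0; it < 100; ++it) {
      if (!std::isfinite(g) || !std::isfinite(g1) || g2 >= -1e-12) break;
      double step = -g1 / g2;
      if (std::fabs(step) < 1e-11 * (1.0 + std::fabs(uhat))) break;
      double unew = uhat + step, gn1, gn2;
      double gn = gval(unew, gn1, gn2);
      int half = 0;
      while ((!std::isfinite(gn) || gn < g) && half < 30) {
        step *= 0.5; unew = uhat + step; gn = gval(unew, gn1, gn2); ++half;
      }
      if (gn < g) break;
      uhat = unew; g = gn; g1 = gn1; g2 = gn2;
      if (std::fabs(g1) < 1e-10 * (1.0 + std::fabs(g))) break;
    }
    double h = (std::isfinite(g2) && g2 < -1e-10) ? -g2 : 1.0 / s2;
    double sc = std::sqrt(2.0 / h);

    double mx = -INFINITY;
    for (int t = 0; t < T; ++t) {
      double d1d, d2d;
      terms[t] = logw[t] + gh_x[t] * gh_x[t] + gval(uhat + sc * gh_x[t],
                                                    d1d, d2d);
      if (terms[t] > mx) mx = terms[t];
    }
    double sum = 0.0;
    for (int t = 0; t < T; ++t) sum += std::exp(terms[t] - mx);
    total += std::log(sc) + mx + std::log(sum);

    // posterior-weighted scores
    std::fill(gz.begin(), gz.end(), 0.0);
    std::fill(gb.begin(), gb.end(), 0.0);
    double gs = 0.0;
    for (int t = 0; t < T; ++t) {
      double w = std::exp(terms[t] - mx) / sum;
      if (w < 1e-14) continue;
      double u = uhat + sc * gh_x[t];
      for (int i = i0; i < i0 + nj; ++i) {
        LP l = logprob(y[i], K, z, m[i] + u);
        if (y[i] < K - 1) gz[y[i]] += w * l.dza;
        if (y[i] > 0)     gz[y[i] - 1] += w * l.dzb;
        for (int r = 0; r < p; ++r) gb[r] += w * l.d1 * X(i, r);
      }
      gs += w * (u * u / s2 - 1.0);    // d/d log sigma of the prior term
    }
    for (int k = 0; k < K - 1; ++k) grad[k] += gz[k];
    for (int r = 0; r < p; ++r) grad[K - 1 + r] += gb[r];
    grad[q - 1] += gs;
  }

  return List::create(_["loglik"] = total, _["grad"] = grad);
}
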