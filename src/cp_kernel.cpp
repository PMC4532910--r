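// Choice-probability kernel for the Bayesian observer models.
//
// Each trial branch reduces to two scalar measurement statistics with
// Gaussian generative distributions N(mu_i, sd_i^2) and observer likelihood
// variances v_i.  The probability of reporting the second interval as
// longer is
//
//   P = Int phi(x1; mu1, sd1) * [1 - Phi((x2*(x1) - mu2)/sd2)] dx1
//
// where x2*(x1) is the decision boundary p(D=1 | x1, x2*) = 1/2.  For the
// flat prior the boundary is exactly x2* = x1 and P has the closed form
// Phi((mu2 - mu1)/sqrt(sd1^2 + sd2^2)).  For non-flat priors the same
// closed form is used as an analytic baseline and order-n Gauss-Hermite
// quadrature integrates only the correction arising from the boundary's
// deviation from x1; the quadrature therefore vanishes exactly when the
// boundary is the identity and stays well conditioned otherwise.
//
// All prior mixture components share variance kappa^2, so the posterior
// component variances within an interval are constant; this is exploited
// throughout.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Mixture {
  std::vector<double> w;   // component weights (sum 1)
  std::vector<double> lw;  // log weights
  std::vector<double> m;   // component means (log duration)
  double var;              // shared component variance kappa^2
};

inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

// Posterior over one interval's duration given measurement x with
// likelihood variance v and mixture prior P: mixture with weights
// alpha_k ~ w_k * phi(x; m_k, var + v), means a*x + (1-a)*m_k and common
// variance a*v, where a = var/(var + v).
struct Posterior {
  std::vector<double> w;
  std::vector<double> mu;
  double V;
  void compute(double x, double v, const Mixture& P) {
    const size_t K = P.w.size();
    w.resize(K);
    mu.resize(K);
    const double denom = P.var + v;
    const double a = P.var / denom;
    V = a * v;
    const double inv2d = 1.0 / (2.0 * denom);
    double wmax = -INFINITY;
    for (size_t k = 0; k < K; ++k) {
      const double d = x - P.m[k];
      w[k] = P.lw[k] - d * d * inv2d;
      if (w[k] > wmax) wmax = w[k];
      mu[k] = a * x + (1.0 - a) * P.m[k];
    }
    double s = 0.0;
    for (size_t k = 0; k < K; ++k) { w[k] = std::exp(w[k] - wmax); s += w[k]; }
    for (size_t k = 0; k < K; ++k) w[k] /= s;
  }
};

inline double phi_cdf(double z) { return norm_cdf(z); }

// p(D = 1) for one prior assignment, with the posterior over t1 already
// computed (it does not move during the boundary search over x2).
double pD1_given_post1(const Posterior& p1, double x2, double v2,
                       const Mixture& P2, Posterior& scratch) {
  scratch.compute(x2, v2, P2);
  const double inv_sd = 1.0 / std::sqrt(p1.V + scratch.V);
  double out = 0.0;
  for (size_t k = 0; k < p1.w.size(); ++k) {
    double acc = 0.0;
    for (size_t l = 0; l < scratch.w.size(); ++l) {
      acc += scratch.w[l] * phi_cdf((scratch.mu[l] - p1.mu[k]) * inv_sd);
    }
    out += p1.w[k] * acc;
  }
  return out;
}

// Decision function g(x2) = p(D=1|x1,x2) - 1/2 for the active prior mode.
// prior_type: 1 = single (pooled prior both intervals), 2 = double
// (average over the two order-conditional assignments).
struct DecisionFun {
  int prior_type;
  double v2;
  const Mixture* A2;       // prior on t2 under assignment A
  const Mixture* B2;       // prior on t2 under assignment B (double only)
  Posterior postA1, postB1, scratch;

  void set_x1(double x1, double v1, const Mixture& A1, const Mixture* B1) {
    postA1.compute(x1, v1, A1);
    if (prior_type == 2) postB1.compute(x1, v1, *B1);
  }
  double operator()(double x2) {
    double p = pD1_given_post1(postA1, x2, v2, *A2, scratch);
    if (prior_type == 2) {
      p = 0.5 * (p + pD1_given_post1(postB1, x2, v2, *B2, scratch));
    }
    return p - 0.5;
  }
};

// Bracketed root search: expand around the flat-prior boundary x1, then
// bisection to tol 1e-10 with a secant acceleration step (safeguarded, so
// the bracket never degrades).  If no sign change is found within the hard
// bracket limit, the whole axis is classified by the sign at the centre.
double find_boundary(DecisionFun& g, double x1, double guess, bool has_guess,
                     bool& bracketed) {
  const double tol = 1e-10;
  double lo, hi, flo, fhi;
  double c = has_guess ? guess : x1;
  double w = 0.25;
  lo = c - w; hi = c + w;
  flo = g(lo); fhi = g(hi);
  int tries = 0;
  while (flo * fhi > 0.0 && tries < 12) {
    w *= 2.5;
    lo = c - w; hi = c + w;
    flo = g(lo); fhi = g(hi);
    ++tries;
  }
  if (flo * fhi > 0.0) {
    bracketed = false;
    // g increasing in x2: positive everywhere => boundary at -Inf
    return (g(c) >= 0.0) ? -INFINITY : INFINITY;
  }
  bracketed = true;
  // Brent's method (inverse quadratic / secant with bisection safeguard)
  double a = lo, b = hi, fa = flo, fb = fhi;
  if (std::abs(fa) < std::abs(fb)) { std::swap(a, b); std::swap(fa, fb); }
  double cc = a, fc = fa, d = b - a, e = d;
  for (int it = 0; it < 200; ++it) {
    if (std::abs(fc) < std::abs(fb)) {
      a = b; b = cc; cc = a;
      fa = fb; fb = fc; fc = fa;
    }
    const double m = 0.5 * (cc - b);
    if (std::abs(m) <= tol || fb == 0.0) return b;
    if (std::abs(e) < tol || std::abs(fa) <= std::abs(fb)) {
      d = e = m;                               // bisection
    } else {
      double p, qq;
      const double s = fb / fa;
      if (a == cc) {                           // secant
        p = 2.0 * m * s;
        qq = 1.0 - s;
      } else {                                 // inverse quadratic
        const double q0 = fa / fc, r = fb / fc;
        p = s * (2.0 * m * q0 * (q0 - r) - (b - a) * (r - 1.0));
        qq = (q0 - 1.0) * (r - 1.0) * (s - 1.0);
      }
      if (p > 0.0) qq = -qq; else p = -p;
      if (2.0 * p < std::min(3.0 * m * qq - std::abs(tol * qq),
                             std::abs(e * qq))) {
        e = d; d = p / qq;
      } else {
        d = e = m;
      }
    }
    a = b; fa = fb;
    b += (std::abs(d) > tol) ? d : (m > 0 ? tol : -tol);
    fb = g(b);
    if ((fb > 0) == (fc > 0)) { cc = a; fc = fa; e = d = b - a; }
  }
  return b;
}

Mixture as_mixture(NumericVector w, NumericVector m, double var) {
  Mixture out;
  out.w.assign(w.begin(), w.end());
  out.m.assign(m.begin(), m.end());
  out.lw.resize(out.w.size());
  for (size_t k = 0; k < out.w.size(); ++k) out.lw[k] = std::log(out.w[k]);
  out.var = var;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cp_batch")]]
NumericVector cp_batch(NumericVector mu1, NumericVector sd1, NumericVector v1,
                       NumericVector mu2, NumericVector sd2, NumericVector v2,
                       int prior_type,
                       NumericVector pr_w, NumericVector pr_m,
                       NumericVector pc_w, NumericVector pc_m,
                       double prior_var,
                       NumericVector gh_x, NumericVector gh_w) {
  const int n = mu1.size();
  NumericVector out(n);

  // flat prior: exact closed form for every row
  if (prior_type == 0) {
    for (int i = 0; i < n; ++i) {
      out[i] = phi_cdf((mu2[i] - mu1[i]) /
                       std::sqrt(sd1[i] * sd1[i] + sd2[i] * sd2[i]));
    }
    return out;
  }

  Mixture Pr = as_mixture(pr_w, pr_m, prior_var);
  Mixture Pc = as_mixture(pc_w, pc_m, prior_var);

  const int q = gh_x.size();
  std::vector<double> node_w(q);
  const double sqrt_pi = std::sqrt(M_PI);
  for (int j = 0; j < q; ++j) node_w[j] = gh_w[j] / sqrt_pi;

  DecisionFun g;
  g.prior_type = prior_type;
  if (prior_type == 1) {        // pooled prior on both intervals
    g.A2 = &Pr; g.B2 = nullptr;
  } else {                      // assignment A: t1 ~ Pc, t2 ~ Pr ("c-r")
    g.A2 = &Pr; g.B2 = &Pc;     // assignment B: t1 ~ Pr, t2 ~ Pc ("r-c")
  }

  // boundary at one x1, for the current (v1, v2) group
  auto boundary_at = [&](double x1, double v1_, double guess,
                         bool has_guess) -> double {
    if (prior_type == 1) {
      g.set_x1(x1, v1_, Pr, nullptr);
    } else {
      g.set_x1(x1, v1_, Pc, &Pr);  // A: t1 ~ Pc; B: t1 ~ Pr
    }
    bool ok;
    return find_boundary(g, x1, guess, has_guess, ok);
  };

  // rows are pre-sorted by (v1, v2, mu1): the decision boundary x2*(x1)
  // is one fixed increasing function per (v1, v2) group.  Small groups are
  // solved node by node with warm starts; large groups solve the boundary
  // on a dense x1 grid once and interpolate it with a C1 monotone cubic,
  // falling back to direct solves if any grid point fails to bracket.
  int i = 0;
  while (i < n) {
    int j1 = i;
    while (j1 < n && v1[j1] == v1[i] && v2[j1] == v2[i] &&
           sd1[j1] == sd1[i] && sd2[j1] == sd2[i]) ++j1;
    const int nrow_g = j1 - i;
    const double v1g = v1[i], v2g = v2[i];
    const double sd1g = sd1[i], sd2g = sd2[i];
    g.v2 = v2g;

    double mu1_min = mu1[i], mu1_max = mu1[i];
    for (int k = i + 1; k < j1; ++k) {
      if (mu1[k] < mu1_min) mu1_min = mu1[k];
      if (mu1[k] > mu1_max) mu1_max = mu1[k];
    }
    const double zmax = std::abs(gh_x[q - 1]);
    const double xlo = mu1_min - M_SQRT2 * sd1g * zmax;
    const double xhi = mu1_max + M_SQRT2 * sd1g * zmax;

    const int GRID = 64;
    const bool use_grid = (nrow_g * q > 2 * GRID) && (xhi > xlo);
    std::vector<double> gx, gy, gd;
    bool grid_ok = false;
    if (use_grid) {
      gx.resize(GRID); gy.resize(GRID);
      const double h = (xhi - xlo) / (GRID - 1);
      grid_ok = true;
      double prev = 0.0; bool havep = false;
      for (int k = 0; k < GRID; ++k) {
        gx[k] = xlo + k * h;
        const double r = boundary_at(gx[k], v1g, prev, havep);
        if (std::isinf(r)) { grid_ok = false; break; }
        gy[k] = r; prev = r; havep = true;
      }
      if (grid_ok) {
        gd.resize(GRID);
        for (int k = 1; k < GRID - 1; ++k) {
          gd[k] = (gy[k + 1] - gy[k - 1]) / (2.0 * h);
        }
        gd[0] = (gy[1] - gy[0]) / h;
        gd[GRID - 1] = (gy[GRID - 1] - gy[GRID - 2]) / h;
      }
    }
    auto interp = [&](double x) -> double {
      const double h = (xhi - xlo) / (GRID - 1);
      int k = (int)((x - xlo) / h);
      if (k < 0) k = 0;
      if (k > GRID - 2) k = GRID - 2;
      const double t = (x - (xlo + k * h)) / h;
      const double t2_ = t * t, t3 = t2_ * t;
      return (2 * t3 - 3 * t2_ + 1) * gy[k] + (t3 - 2 * t2_ + t) * h * gd[k] +
             (-2 * t3 + 3 * t2_) * gy[k + 1] + (t3 - t2_) * h * gd[k + 1];
    };

    double prev_root = 0.0;
    bool have_prev = false;
    for (; i < j1; ++i) {
      const double base = phi_cdf((mu2[i] - mu1[i]) /
                          std::sqrt(sd1g * sd1g + sd2g * sd2g));
      double corr = 0.0;
      for (int j = 0; j < q; ++j) {
        const double x1 = mu1[i] + M_SQRT2 * sd1g * gh_x[j];
        double root;
        if (use_grid && grid_ok) {
          root = interp(x1);
        } else {
          root = boundary_at(x1, v1g, prev_root, have_prev);
        }
        const double tail_flat = phi_cdf((x1 - mu2[i]) / sd2g);
        double tail_true;
        if (std::isinf(root)) {
          tail_true = (root < 0) ? 0.0 : 1.0;
        } else {
          tail_true = phi_cdf((root - mu2[i]) / sd2g);
          prev_root = root;
          have_prev = true;
        }
        corr += node_w[j] * (tail_flat - tail_true);
      }
      double p = base + corr;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      out[i] = p;
    }
  }
  return out;
}
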