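#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bertalanffy-Puetter right-hand side m' = p*m^a - q*m^b, m > 0.
// One log + two exps is cheaper than two pows and shares the log(m).
static inline double bp_rhs(double m, double a, double b, double p, double q) {
  double lm = std::log(m);
  return p * std::exp(a * lm) - q * std::exp(b * lm);
}

// Classical RK4 from (t0, m0) to t1 with at most hmax step size.
// Returns NA_REAL when the state leaves (MLO, MHI) or becomes non-finite;
// callers treat that as a degenerate proposal, not as a penalised score.
static const double MLO = 1e-12, MHI = 1e9;

static double rk4_to(double t0, double m0, double t1,
                     double a, double b, double p, double q, double hmax) {
  double span = t1 - t0;
  if (span <= 0.0) return m0;
  int nstep = (int)std::ceil(span / hmax);
  double h = span / nstep;
  double m = m0;
  for (int i = 0; i < nstep; ++i) {
    double k1 = bp_rhs(m, a, b, p, q);
    double m2 = m + 0.5 * h * k1;
    if (!(m2 > MLO && m2 < MHI)) return NA_REAL;
    double k2 = bp_rhs(m2, a, b, p, q);
    double m3 = m + 0.5 * h * k2;
    if (!(m3 > MLO && m3 < MHI)) return NA_REAL;
    double k3 = bp_rhs(m3, a, b, p, q);
    double m4 = m + h * k3;
    if (!(m4 > MLO && m4 < MHI)) return NA_REAL;
    double k4 = bp_rhs(m4, a, b, p, q);
    m += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!(m > MLO && m < MHI) || !std::isfinite(m)) return NA_REAL;
  }
  return m;
}

// Predicted masses at sorted non-negative times, m(0) = c.
// [[Rcpp::export(name = ".bp_predict_cpp")]]
NumericVector bp_predict_cpp(NumericVector times, double a, double b,
                             double c, double p, double q,
                             double hmax = 0.05) {
  int n = times.size();
  NumericVector out(n);
  double t = 0.0, m = c;
  for (int i = 0; i < n; ++i) {
    m = rk4_to(t, m, times[i], a, b, p, q, hmax);
    if (ISNAN(m)) { std::fill(out.begin() + i, out.end(), NA_REAL); return out; }
    t = times[i];
    out[i] = m;
  }
  return out;
}

// Sum of squared log-errors against precomputed log-masses; NA on degeneracy.
static double ssle_at(const NumericVector& times, const NumericVector& logm,
                      double a, double b, double c, double p, double q,
                      double hmax) {
  double t = 0.0, m = c, s = 0.0;
  int n = times.size();
  for (int i = 0; i < n; ++i) {
    m = rk4_to(t, m, times[i], a, b, p, q, hmax);
    if (ISNAN(m)) return NA_REAL;
    t = times[i];
    double r = logm[i] - std::log(m);
    s += r * r;
  }
  return s;
}

// [[Rcpp::export(name = ".bp_ssle_cpp")]]
double bp_ssle_cpp(NumericVector times, NumericVector logm, double a, double b,
                   double c, double p, double q, double hmax = 0.05) {
  return ssle_at(times, logm, a, b, c, p, q, hmax);
}

// Simulated annealing over (c, p, q) > 0 for fixed exponents (a, b).
// Multiplicative lognormal proposals on all three parameters, geometric
// cooling every cool_every iterations, Metropolis acceptance, then a greedy
// polish (temperature zero, shrinking proposal scale).  Uses R's RNG so runs
// are reproducible under set.seed().  `starts` is a 3 x k matrix of candidate
// (c, p, q) columns; annealing restarts from the incumbent best.
// [[Rcpp::export(name = ".bp_anneal_cpp")]]
List bp_anneal_cpp(NumericVector times, NumericVector logm, double a, double b,
                   NumericMatrix starts, int iters, int restarts,
                   double prop_scale, double t0_frac, double cool_factor,
                   int cool_every, int polish, double hmax = 0.05) {
  RNGScope scope;
  double bc = NA_REAL, bp_ = NA_REAL, bq = NA_REAL, bE = R_PosInf;
  long evals = 0;

  for (int j = 0; j < starts.ncol(); ++j) {
    double E = ssle_at(times, logm, a, b, starts(0, j), starts(1, j),
                       starts(2, j), hmax);
    ++evals;
    if (!ISNAN(E) && E < bE) { bE = E; bc = starts(0, j); bp_ = starts(1, j); bq = starts(2, j); }
  }
  if (!std::isfinite(bE))
    return List::create(_["c"] = NA_REAL, _["p"] = NA_REAL, _["q"] = NA_REAL,
                        _["ssle"] = NA_REAL, _["evals"] = (double)evals);

  for (int r = 0; r < restarts; ++r) {
    double xc = bc, xp = bp_, xq = bq, xE = bE;
    double temp = std::max(bE, 1e-8) * t0_frac;
    for (int it = 0; it < iters; ++it) {
      double yc = xc * std::exp(prop_scale * norm_rand());
      double yp = xp * std::exp(prop_scale * norm_rand());
      double yq = xq * std::exp(prop_scale * norm_rand());
      double yE = ssle_at(times, logm, a, b, yc, yp, yq, hmax);
      ++evals;
      if (!ISNAN(yE)) {  // degenerate trajectories are rejected outright
        double dE = yE - xE;
        if (dE < 0.0 || unif_rand() < std::exp(-dE / temp)) {
          xc = yc; xp = yp; xq = yq; xE = yE;
          if (xE < bE) { bE = xE; bc = xc; bp_ = xp; bq = xq; }
        }
      }
      if ((it + 1) % cool_every == 0) temp *= cool_factor;
    }
  }

  // Greedy polish from the incumbent with a decaying proposal scale.
  double scale = prop_scale;
  for (int it = 0; it < polish; ++it) {
    double yc = bc * std::exp(scale * norm_rand());
    double yp = bp_ * std::exp(scale * norm_rand());
    double yq = bq * std::exp(scale * norm_rand());
    double yE = ssle_at(times, logm, a, b, yc, yp, yq, hmax);
    ++evals;
    if (!ISNAN(yE) && yE < bE) { bE = yE; bc = yc; bp_ = yp; bq = yq; }
    scale *= 0.97;
    if (scale < 1e-5) scale = 1e-5;
  }

  return List::create(_["c"] = bc, _["p"] = bp_, _["q"] = bq,
                      _["ssle"] = bE, _["evals"] = (double)evals);
}
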