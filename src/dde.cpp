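// Constant-delay DDE integration by the method of steps.
//
// An embedded Dormand-Prince 5(4) pair advances the solution with the step
// size capped at the smallest positive delay, so every delayed lookup falls
// on an already-committed solution segment (or the constant pre-initial
// history).  Dense output is cubic Hermite on the committed (t, y, f) nodes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// ----------------------------------------------------------------- dense path

struct DenseTraj {
  std::vector<double> t;   // node times, strictly increasing
  std::vector<double> y;   // node states, row-major (node * dim + j)
  std::vector<double> f;   // node derivatives, same layout
  int dim;
  double t0;
  std::vector<double> hist;  // constant history for s <= t0

  size_t nnodes() const { return t.size(); }

  // Hermite-evaluate component j at time s (s <= last committed node).
  double eval1(double s, int j) const {
    if (s <= t0) return hist[j];
    // binary search for segment [t[i], t[i+1]] containing s
    size_t lo = 0, hi = t.size() - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (t[mid] <= s) lo = mid; else hi = mid;
    }
    double h = t[hi] - t[lo];
    double u = (s - t[lo]) / h;
    double y0 = y[lo * dim + j], y1 = y[hi * dim + j];
    double f0 = f[lo * dim + j], f1 = f[hi * dim + j];
    double u2 = u * u, u3 = u2 * u;
    return (2 * u3 - 3 * u2 + 1) * y0 + (u3 - 2 * u2 + u) * h * f0 +
           (-2 * u3 + 3 * u2) * y1 + (u3 - u2) * h * f1;
  }

  void evalAll(double s, std::vector<double>& out) const {
    for (int j = 0; j < dim; ++j) out[j] = eval1(s, j);
  }
};

// --------------------------------------------------------------- RHS variants

// Interface: fill dy given time, current state, and lagged full states
// (one per delay; lagged[k] is the state at t - delay[k]).
struct RhsBase {
  virtual ~RhsBase() {}
  virtual void eval(double tt, const std::vector<double>& yy,
                    const std::vector<std::vector<double> >& lagged,
                    std::vector<double>& dy) = 0;
};

// Generic R-function callback: rhs(t, y, ylag) with ylag a dim x ndelay matrix.
struct RhsRFunction : public RhsBase {
  Function fn;
  int dim, ndelay;
  RhsRFunction(Function fn_, int dim_, int ndelay_)
    : fn(fn_), dim(dim_), ndelay(ndelay_) {}
  void eval(double tt, const std::vector<double>& yy,
            const std::vector<std::vector<double> >& lagged,
            std::vector<double>& dy) {
    NumericVector yv(yy.begin(), yy.end());
    NumericMatrix lag(dim, ndelay);
    for (int k = 0; k < ndelay; ++k)
      for (int j = 0; j < dim; ++j) lag(j, k) = lagged[k][j];
    NumericVector out = fn(tt, yv, lag);
    if (out.size() != dim) stop("rhs returned length %d, expected %d",
                                (int)out.size(), dim);
    for (int j = 0; j < dim; ++j) dy[j] = out[j];
  }
};

// Five-gene core-clock network.  State order: Bmal1, Rev-Erba, Per2, Cry1,
// Dbp.  Delays are the five transcriptional delays in the same gene order;
// lagged[k][k] is gene k's expression at t - tau_k.  Parameter vector p is
// fixed-order (see R/params.R): tau[0..4], d[0..4], ar1, ar4, cr2, cr3, cr4,
// cr5, gr2, gr3, gr4, gr5, b2, b3, b4, b5, ba2, ba3, ba4, ba5, f2, f3, f4,
// fa2, fa3, fa4.
struct RhsCoreClock : public RhsBase {
  std::vector<double> p;
  RhsCoreClock(const NumericVector& p_) : p(p_.begin(), p_.end()) {
    if (p.size() != 34) stop("core-clock parameter vector must have length 34");
  }
  static double act(double x, double b, double K) {
    return (1.0 + b * x / K) / (1.0 + x / K);
  }
  static double inh(double x, double K) { return 1.0 / (1.0 + x / K); }
  static double ipow(double base, int n) {
    double r = 1.0;
    for (int i = 0; i < n; ++i) r *= base;
    return r;
  }
  void eval(double tt, const std::vector<double>& yy,
            const std::vector<std::vector<double> >& lagged,
            std::vector<double>& dy) {
    (void)tt;
    const double B = lagged[0][0];  // Bmal1(t - tau_Bmal1)
    const double R = lagged[1][1];  // Rev-Erba(t - tau_RevErba)
    const double P = lagged[2][2];  // Per2(t - tau_Per2)
    const double C = lagged[3][3];  // Cry1(t - tau_Cry1)
    const double D = lagged[4][4];  // Dbp(t - tau_Dbp)
    const double dB = p[5], dR = p[6], dP = p[7], dC = p[8], dD = p[9];
    const double ar1 = p[10], ar4 = p[11];
    const double cr2 = p[12], cr3 = p[13], cr4 = p[14], cr5 = p[15];
    const double gr2 = p[16], gr3 = p[17], gr4 = p[18], gr5 = p[19];
    const double b2 = p[20], b3 = p[21], b4 = p[22], b5 = p[23];
    const double ba2 = p[24], ba3 = p[25], ba4 = p[26], ba5 = p[27];
    const double f2 = p[28], f3 = p[29], f4 = p[30];
    const double fa2 = p[31], fa3 = p[32], fa4 = p[33];

    // Bmal1: two RRE inhibition sites
    dy[0] = ipow(inh(R, ar1), 2) - dB * yy[0];
    // Rev-Erba: 3 Ebox (activation x PER inh x CRY inh), 1 Dbox
    dy[1] = ipow(act(B, b2, ba2), 3) * ipow(inh(P, cr2), 3) *
            ipow(inh(C, gr2), 3) * act(D, f2, fa2) - dR * yy[1];
    // Per2: 2 Ebox, 1 Dbox
    dy[2] = ipow(act(B, b3, ba3), 2) * ipow(inh(P, cr3), 2) *
            ipow(inh(C, gr3), 2) * act(D, f3, fa3) - dP * yy[2];
    // Cry1: 2 Ebox, 2 RRE, 1 Dbox
    dy[3] = ipow(act(B, b4, ba4), 2) * ipow(inh(P, cr4), 2) *
            ipow(inh(C, gr4), 2) * ipow(inh(R, ar4), 2) *
            act(D, f4, fa4) - dC * yy[3];
    // Dbp: 3 Ebox
    dy[4] = ipow(act(B, b5, ba5), 3) * ipow(inh(P, cr5), 3) *
            ipow(inh(C, gr5), 3) - dD * yy[4];
  }
};

// Scalar clock-controlled gene forced by delayed evaluations of a committed
// core trajectory (one-way coupling; the CCG state itself is not delayed).
// q = (b, ba, cr, gr, ar, f, fa, d); counts = (n1, n2, n3); taus are the five
// core transcriptional delays in gene order.
struct RhsCcg : public RhsBase {
  std::vector<double> q, tau;
  int n1, n2, n3;
  const DenseTraj* core;
  RhsCcg(const NumericVector& q_, const IntegerVector& counts,
         const NumericVector& tau_, const DenseTraj* core_)
    : q(q_.begin(), q_.end()), tau(tau_.begin(), tau_.end()),
      n1(counts[0]), n2(counts[1]), n3(counts[2]), core(core_) {
    if (q.size() != 8) stop("CCG parameter vector must have length 8");
  }
  void eval(double tt, const std::vector<double>& yy,
            const std::vector<std::vector<double> >& lagged,
            std::vector<double>& dy) {
    (void)lagged;
    const double b = q[0], ba = q[1], cr = q[2], gr = q[3], ar = q[4],
                 f = q[5], fa = q[6], d = q[7];
    double prod = 1.0;
    if (n1 > 0) {
      const double B = core->eval1(tt - tau[0], 0);
      const double P = core->eval1(tt - tau[2], 2);
      const double C = core->eval1(tt - tau[3], 3);
      prod *= std::pow(RhsCoreClock::act(B, b, ba), n1) *
              std::pow(RhsCoreClock::inh(P, cr), n1) *
              std::pow(RhsCoreClock::inh(C, gr), n1);
    }
    if (n2 > 0) {
      const double R = core->eval1(tt - tau[1], 1);
      prod *= std::pow(RhsCoreClock::inh(R, ar), n2);
    }
    if (n3 > 0) {
      const double D = core->eval1(tt - tau[4], 4);
      prod *= std::pow(RhsCoreClock::act(D, f, fa), n3);
    }
    dy[0] = prod - d * yy[0];
  }
};

// ------------------------------------------------------------------ integrator

// Dormand-Prince 5(4) tableau
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3c = 500.0 / 1113, b4c = 125.0 / 192,
             b5c = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order weights for the error estimate
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

struct StageEval {
  RhsBase* rhs;
  const DenseTraj* traj;
  const std::vector<double>* delays;
  int dim;
  std::vector<std::vector<double> > lagged;
  std::vector<double> tmp;

  StageEval(RhsBase* rhs_, const DenseTraj* traj_,
            const std::vector<double>* delays_, int dim_)
    : rhs(rhs_), traj(traj_), delays(delays_), dim(dim_),
      lagged(delays_->size(), std::vector<double>(dim_)), tmp(dim_) {}

  // derivative at (tt, yy); zero delays read the current stage state
  void operator()(double tt, const std::vector<double>& yy,
                  std::vector<double>& dy) {
    for (size_t k = 0; k < delays->size(); ++k) {
      double d = (*delays)[k];
      if (d == 0.0) {
        lagged[k] = yy;
      } else {
        traj->evalAll(tt - d, lagged[k]);
      }
    }
    rhs->eval(tt, yy, lagged, dy);
    for (int j = 0; j < dim; ++j)
      if (!std::isfinite(dy[j]))
        stop("integration failure: non-finite derivative at t = %g", tt);
  }
};

List integrate_impl(RhsBase* rhs, int dim, const std::vector<double>& delays,
                    const std::vector<double>& hist, double t0, double t1,
                    double rtol, double atol, double hmax_user) {
  if (t1 <= t0) stop("t_span must be increasing");
  for (size_t k = 0; k < delays.size(); ++k)
    if (delays[k] < 0) stop("negative delay");

  double min_pos_delay = R_PosInf;
  for (size_t k = 0; k < delays.size(); ++k)
    if (delays[k] > 0 && delays[k] < min_pos_delay) min_pos_delay = delays[k];
  double hmax = hmax_user;
  if (min_pos_delay < hmax) hmax = min_pos_delay;
  if (!(hmax > 0)) stop("hmax must be positive");

  DenseTraj traj;
  traj.dim = dim;
  traj.t0 = t0;
  traj.hist = hist;
  StageEval deriv(rhs, &traj, &delays, dim);

  std::vector<double> y(hist), ynew(dim), yerr(dim), ytmp(dim);
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim);

  double t = t0;
  deriv(t, y, k1);
  traj.t.push_back(t);
  traj.y.insert(traj.y.end(), y.begin(), y.end());
  traj.f.insert(traj.f.end(), k1.begin(), k1.end());

  double h = hmax / 10.0;
  const double hmin = 1e-12 * (t1 - t0);
  long nsteps = 0, nreject = 0;
  const long max_steps = 10000000;

  while (t < t1) {
    if (++nsteps > max_steps) stop("integration failure: step limit at t = %g", t);
    if (h > hmax) h = hmax;
    if (t + h > t1) h = t1 - t;

    // stages
    for (int j = 0; j < dim; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    deriv(t + c2 * h, ytmp, k2);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    deriv(t + c3 * h, ytmp, k3);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    deriv(t + c4 * h, ytmp, k4);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                            a54 * k4[j]);
    deriv(t + c5 * h, ytmp, k5);
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    deriv(t + h, ytmp, k6);
    for (int j = 0; j < dim; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3c * k3[j] + b4c * k4[j] +
                            b5c * k5[j] + b6 * k6[j]);
    deriv(t + h, ynew, k7);  // FSAL

    double errnorm = 0.0;
    for (int j = 0; j < dim; ++j) {
      double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                      e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double q = e / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / dim);

    if (errnorm <= 1.0 || h <= hmin) {
      t += h;
      y = ynew;
      k1 = k7;
      traj.t.push_back(t);
      traj.y.insert(traj.y.end(), y.begin(), y.end());
      traj.f.insert(traj.f.end(), k1.begin(), k1.end());
      double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      ++nreject;
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      if (h < hmin) stop("integration failure: step underflow at t = %g", t);
    }
  }

  size_t n = traj.nnodes();
  NumericVector tv(traj.t.begin(), traj.t.end());
  NumericMatrix ym(n, dim), fm(n, dim);
  for (size_t i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j) {
      ym(i, j) = traj.y[i * dim + j];
      fm(i, j) = traj.f[i * dim + j];
    }
  return List::create(_["t"] = tv, _["y"] = ym, _["f"] = fm,
                      _["t0"] = t0, _["t_end"] = t1,
                      _["history"] = NumericVector(hist.begin(), hist.end()),
                      _["delays"] = NumericVector(delays.begin(), delays.end()),
                      _["dim"] = dim, _["n_steps"] = (double)nsteps,
                      _["n_reject"] = (double)nreject);
}

DenseTraj traj_from_list(const List& tr) {
  DenseTraj d;
  NumericVector t = tr["t"];
  NumericMatrix y = tr["y"], f = tr["f"];
  d.dim = as<int>(tr["dim"]);
  d.t0 = as<double>(tr["t0"]);
  NumericVector h = tr["history"];
  d.hist.assign(h.begin(), h.end());
  d.t.assign(t.begin(), t.end());
  size_t n = d.t.size();
  d.y.resize(n * d.dim);
  d.f.resize(n * d.dim);
  for (size_t i = 0; i < n; ++i)
    for (int j = 0; j < d.dim; ++j) {
      d.y[i * d.dim + j] = y(i, j);
      d.f[i * d.dim + j] = f(i, j);
    }
  return d;
}

}  // namespace

// [[Rcpp::export]]
List dde_integrate_cpp(Function rhs, NumericVector delays,
                       NumericVector history, double t0, double t1,
                       double rtol, double atol, double hmax) {
  int dim = history.size();
  RhsRFunction r(rhs, dim, delays.size());
  std::vector<double> dl(delays.begin(), delays.end());
  std::vector<double> h(history.begin(), history.end());
  return integrate_impl(&r, dim, dl, h, t0, t1, rtol, atol, hmax);
}

// [[Rcpp::export]]
List core_clock_integrate_cpp(NumericVector p, NumericVector history,
                              double t0, double t1, double rtol, double atol,
                              double hmax) {
  RhsCoreClock r(p);
  std::vector<double> dl(p.begin(), p.begin() + 5);  // the five taus
  std::vector<double> h(history.begin(), history.end());
  return integrate_impl(&r, 5, dl, h, t0, t1, rtol, atol, hmax);
}

// [[Rcpp::export]]
List ccg_integrate_cpp(NumericVector q, IntegerVector counts,
                       NumericVector taus, List core_traj, double history,
                       double t0, double t1, double rtol, double atol,
                       double hmax) {
  DenseTraj core = traj_from_list(core_traj);
  RhsCcg r(q, counts, taus, &core);
  std::vector<double> dl;  // no self-delay: plain ODE forced by core
  std::vector<double> h(1, history);
  return integrate_impl(&r, 1, dl, h, t0, t1, rtol, atol, hmax);
}

// [[Rcpp::export]]
NumericMatrix traj_eval_cpp(List traj, NumericVector times) {
  // zero-copy evaluation straight off the stored node arrays
  NumericVector t = traj["t"];
  NumericMatrix y = traj["y"], f = traj["f"];
  int dim = as<int>(traj["dim"]);
  double t0 = as<double>(traj["t0"]);
  NumericVector hist = traj["history"];
  NumericVector delays = traj["delays"];
  int nn = t.size();
  double t_last = t[nn - 1];
  double maxdel = 0.0;
  for (int k = 0; k < delays.size(); ++k)
    if (delays[k] > maxdel) maxdel = delays[k];
  double t_first = t0 - maxdel;  // history region is evaluable
  NumericMatrix out(times.size(), dim);
  for (int i = 0; i < times.size(); ++i) {
    double s = times[i];
    if (s < t_first - 1e-9 || s > t_last + 1e-9)
      stop("evaluation time %g outside trajectory range [%g, %g]", s, t_first,
           t_last);
    if (s > t_last) s = t_last;
    if (s <= t0) {
      for (int j = 0; j < dim; ++j) out(i, j) = hist[j];
      continue;
    }
    int lo = 0, hi = nn - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (t[mid] <= s) lo = mid; else hi = mid;
    }
    double h = t[hi] - t[lo];
    double u = (s - t[lo]) / h;
    double u2 = u * u, u3 = u2 * u;
    double c0 = 2 * u3 - 3 * u2 + 1, c1 = (u3 - 2 * u2 + u) * h;
    double c2c = -2 * u3 + 3 * u2, c3 = (u3 - u2) * h;
    for (int j = 0; j < dim; ++j)
      out(i, j) = c0 * y(lo, j) + c1 * f(lo, j) + c2c * y(hi, j) +
                  c3 * f(hi, j);
  }
  return out;
}
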