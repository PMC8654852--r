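// Compiled kernels: the resident-plus-mutant equilibrium solver (batched over
// mutants, reused across the whole benefit/cost grid) and the agent-based
// simulator's interaction loop.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double ROOT_F_TOL = 1e-11;

// dh/dt = k0 + k1 h + k2 h^2 + k3 h^3 on [0,1]
struct Poly3 {
  double k[4];
  double f(double h) const { return ((k[3] * h + k[2]) * h + k[1]) * h + k[0]; }
  double fp(double h) const { return (3.0 * k[3] * h + 2.0 * k[2]) * h + k[1]; }
  bool is_zero() const {
    for (int i = 0; i < 4; ++i) if (std::fabs(k[i]) > 1e-13) return false;
    return true;
  }
};

static double bisect(const Poly3 &p, double a, double b) {
  double fa = p.f(a);
  for (int it = 0; it < 200; ++it) {
    double m = 0.5 * (a + b), fm = p.f(m);
    if (fm == 0.0 || (b - a) < 1e-16) return m;
    if ((fa > 0) == (fm > 0)) { a = m; fa = fm; } else { b = m; }
  }
  return 0.5 * (a + b);
}

// all roots of p in [0,1]; f is monotone between critical points, and
// tangent roots are caught at critical points / endpoints via |f| tolerance
static int roots01(const Poly3 &p, double *out) {
  double br[4];
  int nb = 0;
  br[nb++] = 0.0;
  double a2 = 3.0 * p.k[3], a1 = 2.0 * p.k[2], a0 = p.k[1];
  if (std::fabs(a2) > 1e-13) {
    double disc = a1 * a1 - 4.0 * a2 * a0;
    if (disc >= 0.0) {
      double s = std::sqrt(disc);
      double r1 = (-a1 - s) / (2.0 * a2), r2 = (-a1 + s) / (2.0 * a2);
      if (r1 > r2) std::swap(r1, r2);
      if (r1 > 0.0 && r1 < 1.0) br[nb++] = r1;
      if (r2 > 0.0 && r2 < 1.0 && r2 != r1) br[nb++] = r2;
    }
  } else if (std::fabs(a1) > 1e-13) {
    double r = -a0 / a1;
    if (r > 0.0 && r < 1.0) br[nb++] = r;
  }
  br[nb++] = 1.0;
  // breakpoints are already sorted (crit roots ordered, within (0,1))
  double roots[6];
  int nr = 0;
  for (int i = 0; i < nb; ++i)
    if (std::fabs(p.f(br[i])) < ROOT_F_TOL) roots[nr++] = br[i];
  for (int i = 0; i + 1 < nb; ++i) {
    double fa = p.f(br[i]), fb = p.f(br[i + 1]);
    if (fa * fb < 0.0) roots[nr++] = bisect(p, br[i], br[i + 1]);
  }
  // sort + dedupe
  for (int i = 1; i < nr; ++i)
    for (int j = i; j > 0 && roots[j] < roots[j - 1]; --j)
      std::swap(roots[j], roots[j - 1]);
  int m = 0;
  for (int i = 0; i < nr; ++i)
    if (m == 0 || roots[i] - out[m - 1] > 1e-9) out[m++] = roots[i];
  return m;
}

// forward-flow endpoint from h0 (limit of time integration, computed exactly)
static double flow_endpoint(const Poly3 &p, double h0, bool *marginal) {
  *marginal = false;
  if (p.is_zero()) { *marginal = true; return h0; }
  double f0 = p.f(h0);
  if (std::fabs(f0) < ROOT_F_TOL) return h0;
  double r[6];
  int n = roots01(p, r);
  if (f0 > 0.0) {
    for (int i = 0; i < n; ++i) if (r[i] > h0 + 1e-12) return r[i];
    return 1.0;
  }
  for (int i = n - 1; i >= 0; --i) if (r[i] < h0 - 1e-12) return r[i];
  return 0.0;
}

static inline double qerr(double x, double mu_a) {
  return x * (1.0 - mu_a) + (1.0 - x) * mu_a;
}

struct Bits {
  int a1, a0;
  double qc[4], qd[4];  // order 11,10,01,00, assessment error applied
  void load(const int *b, double mu_a) {
    a1 = b[0]; a0 = b[1];
    for (int i = 0; i < 4; ++i) {
      qc[i] = qerr((double)b[2 + i], mu_a);
      qd[i] = qerr((double)b[6 + i], mu_a);
    }
  }
  double act(double h, double mu_e) const {
    double raw = h * a1 + (1.0 - h) * a0;
    return raw * (1.0 - 2.0 * mu_e) + mu_e;
  }
};

// Resident-plus-rare-mutant equilibria for one resident against a batch of
// mutants.  The resident h-score h_rr is pre-equilibrated (autonomous) and
// passed in.  The remaining system in (x, y) = (h_mr, h_rm):
//   dy/dt = g2(y)       (mutant judging resident-resident interactions)
//   dx/dt = a(y)(1-x) + (b(y)-1)x   with
//     a(y) = pM(y)*qC0 + (1-pM(y))*qD0,  b(y) = pM(y)*qC1 + (1-pM(y))*qD1,
//   qC1 = q(c11) r + q(c10)(1-r) etc. from the RESIDENT's assessment rules,
//   pM(y) = mutant's cooperation probability toward residents.
// y* comes from the exact flow endpoint of the (quadratic) g2; x is linear
// and contracts at rate a+1-b >= 0, so whenever a*+1-b* > 0 its limit is
// a*/(a*+1-b*) regardless of the transient.  Only the marginal case
// (a*+1-b* ~ 0) needs the coupled transient, integrated numerically.
//
// Returns one row per mutant:
//   h_mr, h_rm, eig_x, eig_y, converged, steps, residual, cycle_flag
// [[Rcpp::export]]
NumericMatrix solve_dimorphic_batch(IntegerVector res_bits, double h_rr_star,
                                    IntegerMatrix mut_bits, double h0,
                                    double mu_e, double mu_a,
                                    double tol = 1e-10, double t_max = 1e6) {
  if (res_bits.size() != 10) stop("resident must have 10 bits");
  if (mut_bits.ncol() != 10) stop("mutant matrix must have 10 columns");
  const int n = mut_bits.nrow();
  Bits res;
  res.load(&res_bits[0], mu_a);
  const double r = h_rr_star;
  const double qC1 = res.qc[0] * r + res.qc[1] * (1.0 - r);
  const double qC0 = res.qc[2] * r + res.qc[3] * (1.0 - r);
  const double qD1 = res.qd[0] * r + res.qd[1] * (1.0 - r);
  const double qD0 = res.qd[2] * r + res.qd[3] * (1.0 - r);
  const double p_res = res.act(r, mu_e);  // resident donor toward residents

  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("h_mr", "h_rm", "eig_x", "eig_y",
                                          "converged", "steps", "residual",
                                          "cycle_flag");
  int mb[10];
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < 10; ++t) mb[t] = mut_bits(j, t);
    Bits mut;
    mut.load(mb, mu_a);
    // g2(y): mutant observer of resident-resident interaction; both of the
    // mutant's opinions are Bernoulli(y); donor's visible action has
    // constant probability p_res
    Poly3 g2;
    {
      // S(y) = q00 + (q10+q01-2q00) y + (q11-q10-q01+q00) y^2, mixed by p_res
      double sc0 = mut.qc[3], sc1 = mut.qc[1] + mut.qc[2] - 2.0 * mut.qc[3],
             sc2 = mut.qc[0] - mut.qc[1] - mut.qc[2] + mut.qc[3];
      double sd0 = mut.qd[3], sd1 = mut.qd[1] + mut.qd[2] - 2.0 * mut.qd[3],
             sd2 = mut.qd[0] - mut.qd[1] - mut.qd[2] + mut.qd[3];
      g2.k[0] = sd0 + p_res * (sc0 - sd0);
      g2.k[1] = sd1 + p_res * (sc1 - sd1) - 1.0;
      g2.k[2] = sd2 + p_res * (sc2 - sd2);
      g2.k[3] = 0.0;
    }
    bool y_marginal;
    double y_star = flow_endpoint(g2, h0, &y_marginal);
    double eig_y = y_marginal ? 0.0 : g2.fp(y_star);

    auto alpha = [&](double y) {
      double pM = mut.act(y, mu_e);
      return pM * qC0 + (1.0 - pM) * qD0;
    };
    auto beta = [&](double y) {
      double pM = mut.act(y, mu_e);
      return pM * qC1 + (1.0 - pM) * qD1;
    };
    double a_star = alpha(y_star), b_star = beta(y_star);
    double denom = a_star + 1.0 - b_star;  // contraction rate, >= 0
    double x_star, steps = 0, converged = 1, cycle = 0;
    if (denom > 1e-9) {
      x_star = a_star / denom;
    } else if (std::fabs(alpha(0.0)) < 1e-13 && std::fabs(alpha(1.0)) < 1e-13 &&
               std::fabs(beta(0.0) - 1.0) < 1e-13 &&
               std::fabs(beta(1.0) - 1.0) < 1e-13) {
      // dx/dt vanishes identically (alpha and beta are affine in y):
      // h_mr is frozen at the shared initial condition
      x_star = h0;
    } else {
      // marginal x at the limit: the endpoint is h0 plus whatever drifts in
      // while y relaxes, so the coupled transient matters.  y is autonomous
      // and x is linear in x given y, so each step advances y by an
      // RK4 update and x by
      // the exact solution of its frozen-coefficient linear equation at the
      // midpoint y.  A coarse/fine pair of runs provides error control.
      auto expstep = [&](double y0, double h) -> double {
        // classic RK4; the rate-scaled dt keeps |lambda| h well inside the
        // stability region
        double k1 = g2.f(y0);
        double k2 = g2.f(y0 + 0.5 * h * k1);
        double k3 = g2.f(y0 + 0.5 * h * k2);
        double k4 = g2.f(y0 + h * k3);
        double yn = y0 + h * (k1 + 2.0 * k2 + 2.0 * k3 + k4) / 6.0;
        return std::min(std::max(yn, 0.0), 1.0);
      };
      auto run_transient = [&](double frac, double &x_end, double &y_end,
                               double &t_end, double &nsteps) -> bool {
        double x = h0, y = h0, t = 0.0;
        long n = 0;
        const long n_max = 2000000;
        bool ok = false;
        while (n < n_max && t < t_max) {
          double gy = g2.f(y);
          double gx = alpha(y) * (1.0 - x) + (beta(y) - 1.0) * x;
          if (std::fabs(gy) + std::fabs(gx) < tol) { ok = true; break; }
          double bnow = alpha(y) + 1.0 - beta(y);
          double rate = std::max({std::fabs(g2.fp(y)), bnow, 0.01});
          double dt = std::min(frac / rate, 50.0);
          double ymid = expstep(y, 0.5 * dt);
          double a = alpha(ymid), b = a + 1.0 - beta(ymid);
          if (b > 1e-14) {
            double e = std::exp(-b * dt);
            x = x * e + (a / b) * (1.0 - e);
          } else {
            x += dt * (a * (1.0 - x) + (beta(ymid) - 1.0) * x);
          }
          x = std::min(std::max(x, 0.0), 1.0);
          y = expstep(y, dt);
          t += dt; ++n;
        }
        x_end = x; y_end = y; t_end = t; nsteps = (double)n;
        return ok;
      };
      double x1, y1, t1, n1, x2, y2, t2, n2;
      run_transient(0.10, x1, y1, t1, n1);
      bool ok2 = run_transient(0.05, x2, y2, t2, n2);
      double diff = std::fabs(x1 - x2);
      int halvings = 0;
      double frac = 0.05;
      while (diff > 1e-8 && halvings < 4) {
        x1 = x2;
        frac *= 0.5; ++halvings;
        ok2 = run_transient(frac, x2, y2, t2, n2);
        diff = std::fabs(x1 - x2);
      }
      x_star = x2;
      steps = n2;
      converged = (ok2 && diff <= 1e-6) ? 1 : 0;
      if (!ok2) cycle = 1;
      if (std::fabs(y2 - y_star) > 1e-6) y_star = y2;
    }
    double resid = std::fabs(alpha(y_star) * (1.0 - x_star) +
                             (beta(y_star) - 1.0) * x_star) +
                   std::fabs(g2.f(y_star));
    out(j, 0) = std::min(std::max(x_star, 0.0), 1.0);
    out(j, 1) = std::min(std::max(y_star, 0.0), 1.0);
    out(j, 2) = b_star - 1.0 - a_star;  // d(gx)/dx
    out(j, 3) = eig_y;
    out(j, 4) = converged;
    out(j, 5) = steps;
    out(j, 6) = resid;
    out(j, 7) = cycle;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Agent-based model: one donation-game interaction per step, one observer.

// [[Rcpp::export]]
NumericMatrix run_abm_cpp(IntegerVector bits, int N, int total_interactions,
                          int window, int reps, double h0, double mu_e,
                          double mu_a, int seed,
                          bool observer_can_be_recipient = false) {
  if (bits.size() != 10) stop("strategy must have 10 bits");
  if (N < 3) stop("population size must be at least 3");
  if (window > total_interactions) stop("averaging window exceeds run length");
  const int a1 = bits[0], a0 = bits[1];
  int crule[4], drule[4];
  for (int i = 0; i < 4; ++i) { crule[i] = bits[2 + i]; drule[i] = bits[6 + i]; }

  NumericMatrix out(reps, 2);
  colnames(out) = CharacterVector::create("mean_h", "mean_coop");
  const double denom = (double)N * (N - 1);

  for (int rep = 0; rep < reps; ++rep) {
    // per-replicate substream: independent generator seeded from (seed, rep)
    std::seed_seq sseq{(std::uint32_t)seed, (std::uint32_t)(rep + 1)};
    std::mt19937_64 rng(sseq);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::uniform_int_distribution<int> pick(0, N - 1);

    std::vector<std::uint8_t> op((size_t)N * N, 0);
    long ones = 0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (i != j && unif(rng) < h0) { op[(size_t)i * N + j] = 1; ++ones; }

    double h_acc = 0.0;
    long coop_acc = 0;
    const int burn = total_interactions - window;
    for (int step = 0; step < total_interactions; ++step) {
      int donor = pick(rng);
      int recip = pick(rng);
      while (recip == donor) recip = pick(rng);
      int intended = op[(size_t)donor * N + recip] ? a1 : a0;
      int action = (unif(rng) < mu_e) ? 1 - intended : intended;
      int obs = pick(rng);
      while (obs == donor || (!observer_can_be_recipient && obs == recip))
        obs = pick(rng);
      if (obs != donor) {
        int i = op[(size_t)obs * N + donor];
        int k = op[(size_t)obs * N + recip];
        int idx = (1 - i) * 2 + (1 - k);
        int newop = action ? crule[idx] : drule[idx];
        if (unif(rng) < mu_a) newop = 1 - newop;
        std::uint8_t &cell = op[(size_t)obs * N + donor];
        ones += newop - (int)cell;
        cell = (std::uint8_t)newop;
      }
      if (step >= burn) {
        h_acc += (double)ones / denom;
        coop_acc += action;
      }
    }
    out(rep, 0) = h_acc / window;
    out(rep, 1) = (double)coop_acc / window;
  }
  return out;
}
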