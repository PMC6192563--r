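#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Shifted logistic S(x) = 1/(1+exp(-a(x-th))) - 1/(1+exp(a*th)); S(0) = 0.
static inline double sigm(double x, double a, double th, double corr) {
  return 1.0 / (1.0 + std::exp(-a * (x - th))) - corr;
}

// Delay-coupled Wilson-Cowan network, midpoint (second-order) Runge-Kutta.
//
// State histories are kept for the whole run (they are also the returned
// traces). Delayed values older than t=0 take the initial condition. The
// midpoint stage uses linearly interpolated history for delayed terms
// (current-stage midpoint values for zero-delay edges). Additive noise
// sigma*N(0,1) is applied to each state variable once per step, after the
// deterministic update, drawing from R's RNG so runs are seed-reproducible.
//
// A:        n x n symmetric weight matrix
// Dsteps:   n x n integer delay matrix, units of the step h
// sched:    m x 4 matrix (0-based region, amplitude, onset step, offset step)
//           P_i(t) sums all rows covering region i with onset <= s < offset
// [[Rcpp::export]]
List wc_integrate(NumericMatrix A, IntegerMatrix Dsteps, List par,
                  NumericMatrix sched, int n_steps, double init) {
  const int n = A.nrow();
  const double c1 = par["c1"], c2 = par["c2"], c3 = par["c3"], c4 = par["c4"];
  const double c5 = par["c5"], c6 = par["c6"];
  const double aE = par["a_E"], aI = par["a_I"];
  const double thE = par["theta_E"], thI = par["theta_I"];
  const double tau = par["tau"], sigma = par["sigma"], h = par["step_h"];
  const double SEmax = par["S_E_max"], SImax = par["S_I_max"];
  const double corrE = 1.0 / (1.0 + std::exp(aE * thE));
  const double corrI = 1.0 / (1.0 + std::exp(aI * thI));

  // CSR layout over nonzero weights of the (symmetric) matrix
  std::vector<int> ptr(n + 1, 0);
  std::vector<int> nb, dl;
  std::vector<double> wt;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      if (A(j, i) != 0.0) {
        nb.push_back(j);
        wt.push_back(A(j, i));
        dl.push_back(Dsteps(j, i));
      }
    ptr[i + 1] = (int)nb.size();
  }

  NumericMatrix Etr(n, n_steps + 1), Itr(n, n_steps + 1);
  double *E = REAL(Etr), *I = REAL(Itr);
  for (int i = 0; i < n; ++i) { E[i] = init; I[i] = init; }

  std::vector<double> P(n), k1E(n), k1I(n), Em(n), Im(n), cE(n), cI(n);
  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    std::fill(P.begin(), P.end(), 0.0);
    for (int r = 0; r < sched.nrow(); ++r) {
      if (s >= sched(r, 2) && s < sched(r, 3))
        P[(int)sched(r, 0)] += sched(r, 1);
    }
    const double *Ecur = E + (size_t)s * n, *Icur = I + (size_t)s * n;

    // stage 1: delayed terms at t
    for (int i = 0; i < n; ++i) {
      double sE = 0.0, sI = 0.0;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        const int idx = s - dl[k];
        const double w = wt[k];
        if (idx >= 0) {
          const size_t off = (size_t)idx * n + nb[k];
          sE += w * E[off];
          sI += w * I[off];
        } else {
          sE += w * init;
          sI += w * init;
        }
      }
      cE[i] = sE; cI[i] = sI;
    }
    for (int i = 0; i < n; ++i) {
      const double e = Ecur[i], ii = Icur[i];
      k1E[i] = (-e + (SEmax - e) *
                sigm(c1 * e - c2 * ii + c5 * cE[i] + P[i], aE, thE, corrE)) / tau;
      k1I[i] = (-ii + (SImax - ii) *
                sigm(c3 * e - c4 * ii + c6 * cI[i], aI, thI, corrI)) / tau;
      Em[i] = e + 0.5 * h * k1E[i];
      Im[i] = ii + 0.5 * h * k1I[i];
    }

    // stage 2: delayed terms at t + h/2 (interpolated history; midpoint
    // state itself for zero-delay edges)
    for (int i = 0; i < n; ++i) {
      double sE = 0.0, sI = 0.0;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        const int j = nb[k], d = dl[k];
        const double w = wt[k];
        if (d == 0) {
          sE += w * Em[j];
          sI += w * Im[j];
        } else {
          const int lo = s - d;
          const size_t offhi = (size_t)(lo + 1) * n + j;
          const double elo = lo >= 0 ? E[offhi - n] : init;
          const double ilo = lo >= 0 ? I[offhi - n] : init;
          const double ehi = lo + 1 >= 0 ? E[offhi] : init;
          const double ihi = lo + 1 >= 0 ? I[offhi] : init;
          sE += w * 0.5 * (elo + ehi);
          sI += w * 0.5 * (ilo + ihi);
        }
      }
      cE[i] = sE; cI[i] = sI;
    }
    double *Enext = E + (size_t)(s + 1) * n, *Inext = I + (size_t)(s + 1) * n;
    for (int i = 0; i < n; ++i) {
      const double e = Em[i], ii = Im[i];
      const double k2E = (-e + (SEmax - e) *
        sigm(c1 * e - c2 * ii + c5 * cE[i] + P[i], aE, thE, corrE)) / tau;
      const double k2I = (-ii + (SImax - ii) *
        sigm(c3 * e - c4 * ii + c6 * cI[i], aI, thI, corrI)) / tau;
      double En = Ecur[i] + h * k2E;
      double In = Icur[i] + h * k2I;
      if (sigma > 0.0) {
        En += sigma * norm_rand();
        In += sigma * norm_rand();
      }
      if (!std::isfinite(En) || !std::isfinite(In) ||
          std::abs(En) > 10.0 || std::abs(In) > 10.0)
        stop("integration diverged at step %d (t = %.1f ms)", s + 1,
             (s + 1) * h);
      Enext[i] = En;
      Inext[i] = In;
    }
  }
  return List::create(_["E"] = Etr, _["I"] = Itr);
}

// Pairwise maximum-lag Pearson cross-correlation on a (possibly strided)
// segment of excitatory traces. X is n_samples x n_regions. For each pair,
// correlations are computed on overlapping samples at every integer lag in
// [-max_lag, max_lag] and the signed maximum is kept. Pairs involving a
// constant signal are NA; the diagonal is 1 where defined.
// [[Rcpp::export]]
NumericMatrix fc_max_lag(NumericMatrix X, int max_lag) {
  const int T = X.nrow(), n = X.ncol();
  if (max_lag >= T - 2) stop("max_lag too large for the window");
  NumericMatrix FC(n, n);
  const double *x = REAL(X);
  std::vector<bool> flat(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = x + (size_t)i * T;
    double mn = xi[0], mx = xi[0];
    for (int t = 1; t < T; ++t) {
      if (xi[t] < mn) mn = xi[t];
      if (xi[t] > mx) mx = xi[t];
    }
    flat[i] = (mx == mn);
  }
  for (int i = 0; i < n; ++i)
    FC(i, i) = flat[i] ? NA_REAL : 1.0;

  for (int i = 0; i < n; ++i) {
    const double *xi = x + (size_t)i * T;
    for (int j = i + 1; j < n; ++j) {
      if (flat[i] || flat[j]) { FC(i, j) = FC(j, i) = NA_REAL; continue; }
      const double *xj = x + (size_t)j * T;
      double best = R_NegInf;
      bool any = false;
      for (int lag = -max_lag; lag <= max_lag; ++lag) {
        // overlap of x[t] with y[t + lag]
        const int t0 = std::max(0, -lag);
        const int t1 = std::min(T, T - lag);
        const int m = t1 - t0;
        if (m < 3) continue;
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        for (int t = t0; t < t1; ++t) {
          const double a = xi[t], b = xj[t + lag];
          sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
        }
        const double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
        if (vx <= 0 || vy <= 0) continue;
        double r = (sxy - sx * sy / m) / std::sqrt(vx * vy);
        if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
        if (r > best) best = r;
        any = true;
      }
      FC(i, j) = FC(j, i) = any ? best : NA_REAL;
    }
  }
  return FC;
}
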