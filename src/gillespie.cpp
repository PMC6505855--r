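#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear vaccine uptake nu(t), clipped to [0, 1].
static double nu_at(double t, const NumericVector& tt, const NumericVector& vv) {
  int n = tt.size();
  double v;
  if (n == 1 || t <= tt[0]) {
    v = vv[0];
  } else if (t >= tt[n - 1]) {
    v = vv[n - 1];
  } else {
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (tt[mid] <= t) lo = mid; else hi = mid;
    }
    double w = (t - tt[lo]) / (tt[hi] - tt[lo]);
    v = vv[lo] + w * (vv[hi] - vv[lo]);
  }
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// Exact event-driven (SSA) simulation of the SIR model with vaccination at
// birth and sparking.  Six events: birth of a susceptible at rate b(1-nu),
// death of a susceptible at mu*S, transmission at beta*S*I, sparking at
// eta*S (S -> I), recovery at gamma*I, death of an infected at mu*I.
// For time-varying nu the rates are refreshed at most every `refresh` years
// (the scheme is exact between refreshes, and exact throughout when nu is
// constant).  Uses R's RNG, so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
List gillespie_cpp(double b, double mu, double gamma, double eta, double beta,
                   double S0, double I0, double T, double sample_dt,
                   NumericVector nu_times, NumericVector nu_values,
                   double refresh) {
  const bool constant_nu = (nu_times.size() <= 1);
  const int n_samp = (int)std::floor(T / sample_dt + 1e-9) + 1;
  NumericVector out_t(n_samp), out_S(n_samp), out_I(n_samp), out_nu(n_samp);

  double S = S0, I = I0, t = 0.0;
  int k = 0; // next sample index

  while (true) {
    double nu = nu_at(t, nu_times, nu_values);
    double r1 = b * (1.0 - nu);
    double r2 = mu * S;
    double r3 = beta * S * I;
    double r4 = eta * S;
    double r5 = gamma * I;
    double r6 = mu * I;
    double R = r1 + r2 + r3 + r4 + r5 + r6;
    if (!R_finite(R) || R < 0.0)
      stop("event rate overflow or negative rate at t = %f", t);

    double block_end = constant_nu ? T : std::min(t + refresh, T);
    double t_next;
    bool fire = false;
    if (R <= 0.0) {
      t_next = block_end;
    } else {
      double dt = exp_rand() / R;
      if (t + dt >= block_end) {
        t_next = block_end;
      } else {
        t_next = t + dt;
        fire = true;
      }
    }

    // state is constant on [t, t_next); record samples falling in it
    while (k < n_samp && k * sample_dt <= t_next + 1e-12) {
      double ts = k * sample_dt;
      out_t[k] = ts;
      out_S[k] = S;
      out_I[k] = I;
      out_nu[k] = nu_at(ts, nu_times, nu_values);
      ++k;
    }

    t = t_next;
    if (fire) {
      double u = unif_rand() * R;
      if (u < r1)                          S += 1;
      else if (u < r1 + r2)                S -= 1;
      else if (u < r1 + r2 + r3)         { S -= 1; I += 1; }
      else if (u < r1 + r2 + r3 + r4)    { S -= 1; I += 1; }
      else if (u < r1 + r2 + r3 + r4 + r5) I -= 1;
      else                                 I -= 1;
    }
    if (t >= T || k >= n_samp) break;
  }
  // pad any remaining grid points (possible when all rates hit zero)
  while (k < n_samp) {
    double ts = k * sample_dt;
    out_t[k] = ts;
    out_S[k] = S;
    out_I[k] = I;
    out_nu[k] = nu_at(ts, nu_times, nu_values);
    ++k;
  }
  return List::create(_["t"] = out_t, _["S"] = out_S, _["I"] = out_I,
                      _["nu"] = out_nu);
}
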