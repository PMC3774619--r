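#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-n Metropolis-Hastings sampler for the Strauss process on a
// rectangular window. A uniformly chosen point is proposed to move to a
// uniform location; the move is accepted with probability
// min(1, gamma^(t_new - t_old)), where t_* are the neighbour counts of the
// moved point within distance r. gamma = 0 (hard core) starts from a random
// sequential packing and accepts only conflict-free moves. Uses R's RNG so
// runs are reproducible under set.seed().
// [[Rcpp::export]]
List strauss_mh_cpp(int n, double gamma, double r, double wx, double wy,
                    int burnin, int steps, int max_pack_tries) {
  std::vector<double> x(n), y(n);
  const double r2 = r * r;
  RNGScope scope;

  if (gamma == 0.0) {
    int placed = 0;
    long tries = 0;
    while (placed < n) {
      if (++tries > (long)max_pack_tries)
        stop("packing error: could not place %d hard-core points", n);
      double px = unif_rand() * wx, py = unif_rand() * wy;
      bool ok = true;
      for (int j = 0; j < placed; ++j) {
        double dx = px - x[j], dy = py - y[j];
        if (dx * dx + dy * dy <= r2) { ok = false; break; }
      }
      if (ok) { x[placed] = px; y[placed] = py; ++placed; }
    }
  } else {
    for (int i = 0; i < n; ++i) {
      x[i] = unif_rand() * wx;
      y[i] = unif_rand() * wy;
    }
  }

  long s_curr = 0;
  for (int i = 1; i < n; ++i)
    for (int j = 0; j < i; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) ++s_curr;
    }

  const long total = (long)burnin + (long)steps;
  const double lg = (gamma > 0.0) ? std::log(gamma) : 0.0;
  const long trace_every = n > 0 ? n : 1;
  std::vector<double> s_trace;
  s_trace.reserve(total / trace_every + 2);

  for (long it = 0; it < total; ++it) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    double px = unif_rand() * wx, py = unif_rand() * wy;
    int told = 0, tnew = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) ++told;
      dx = px - x[j]; dy = py - y[j];
      if (dx * dx + dy * dy <= r2) ++tnew;
    }
    bool accept;
    if (gamma == 0.0) {
      accept = (tnew == 0);
    } else {
      int ds = tnew - told;
      accept = (ds <= 0) || (unif_rand() < std::exp(lg * (double)ds));
    }
    if (accept) {
      x[i] = px;
      y[i] = py;
      s_curr += tnew - told;
    }
    if (it % trace_every == 0) s_trace.push_back((double)s_curr);
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = y[i];
  }
  return List::create(_["points"] = out,
                      _["s_trace"] = NumericVector(s_trace.begin(), s_trace.end()));
}
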