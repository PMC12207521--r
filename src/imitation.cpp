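// Compiled inner loops for the stochastic imitation dynamics.
// All randomness comes from R's RNG (seed with set.seed() on the R side).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// sample an index 0..(n-1) proportional to non-negative weights w
static int sample_weighted(const std::vector<double>& w) {
  double tot = 0.0;
  for (double v : w) tot += v;
  double u = unif_rand() * tot;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  return n - 1;
}

// Imitation process over a pairwise matrix game.
// A: m x m payoff matrix (row against column); C: m x m cooperation rates
// (row strategy's rate against column). Focal uniform; exploration mu
// uniform over the full set; otherwise role model among the other N-1
// individuals with weight count * exp(beta * (payoff - max payoff)).
// Payoffs exclude self-interaction. Post burn-in, accumulates strategy
// abundances and the population-matched expected cooperation rate.
// [[Rcpp::export]]
List run_imitation_pairwise(NumericMatrix A, NumericMatrix C, int N,
                            double beta, double mu, int steps, int burn_in,
                            IntegerVector init) {
  int m = A.nrow();
  if (A.ncol() != m || C.nrow() != m || C.ncol() != m)
    stop("A and C must be square with matching dimension");
  if (init.size() != m) stop("init must have one count per strategy");
  std::vector<long long> counts(m);
  long long tot = 0;
  for (int s = 0; s < m; ++s) { counts[s] = init[s]; tot += init[s]; }
  if (tot != N) stop("init counts must sum to N");

  std::vector<double> pay(m), w(m), abund(m, 0.0);
  double coop_sum = 0.0;
  long long kept = 0;
  RNGScope scope;

  for (int step = 1; step <= steps; ++step) {
    // focal individual's strategy
    int focal;
    {
      double u = unif_rand() * N, acc = 0.0;
      focal = m - 1;
      for (int s = 0; s < m; ++s) {
        acc += counts[s];
        if (u < acc) { focal = s; break; }
      }
    }
    int adopt;
    if (unif_rand() < mu) {
      adopt = (int)(unif_rand() * m);
      if (adopt == m) adopt = m - 1;
    } else {
      double pimax = -1e300;
      for (int s = 0; s < m; ++s) {
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += A(s, j) * counts[j];
        pay[s] = (acc - A(s, s)) / (N - 1);
        long long avail = counts[s] - (s == focal ? 1 : 0);
        if (avail > 0 && pay[s] > pimax) pimax = pay[s];
      }
      for (int s = 0; s < m; ++s) {
        long long avail = counts[s] - (s == focal ? 1 : 0);
        w[s] = avail > 0 ? (double)avail * std::exp(beta * (pay[s] - pimax)) : 0.0;
      }
      adopt = sample_weighted(w);
    }
    counts[focal] -= 1;
    counts[adopt] += 1;

    if (step > burn_in) {
      ++kept;
      double num = 0.0;
      for (int i = 0; i < m; ++i) {
        if (counts[i] == 0) continue;
        for (int j = 0; j < m; ++j) {
          double nj = (double)counts[j] - (i == j ? 1.0 : 0.0);
          if (nj > 0) num += (double)counts[i] * nj * C(i, j);
        }
        abund[i] += counts[i];
      }
      coop_sum += num / ((double)N * (N - 1));
    }
  }
  NumericVector ab(m);
  for (int s = 0; s < m; ++s) ab[s] = abund[s] / ((double)kept * N);
  return List::create(_["abundances"] = ab,
                      _["coop_index"] = coop_sum / (double)kept);
}
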