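// Compiled donation-game / reputation dynamics for indirect reciprocity.
//
// Encoding: action 1 = C, 0 = D; reputation 1 = G, 0 = B.
// rules: m x 2 integer matrix (act_on_G, act_on_B).
// norms: m x 4 integer matrix, column 2*action + reputation:
//        (D,B), (D,G), (C,B), (C,G); entries are the assigned reputation.
// Opinions are private: op[k*N + j] is agent k's opinion of agent j; the
// diagonal holds each agent's self-image, updated when it acts as donor
// (the donor judges itself with its own norm).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct IrCore {
  int N, m;
  std::vector<int> rul;   // m x 2 flat: act_on_G, act_on_B
  std::vector<int> nrm;   // m x 4 flat: (D,B) (D,G) (C,B) (C,G)
  double benefit, cost, a_err, e_err;
  std::vector<int> strat;
  std::vector<int> op;

  IrCore(const IntegerMatrix& rules_, const IntegerMatrix& norms_,
         int N_, double benefit_, double cost_, double a_err_, double e_err_,
         const IntegerVector& init)
    : N(N_), m(rules_.nrow()),
      benefit(benefit_), cost(cost_), a_err(a_err_), e_err(e_err_),
      strat(N_), op((size_t)N_ * N_, 1) {
    rul.resize((size_t)m * 2);
    nrm.resize((size_t)m * 4);
    for (int s = 0; s < m; ++s) {
      rul[s * 2 + 0] = rules_(s, 0);
      rul[s * 2 + 1] = rules_(s, 1);
      for (int c = 0; c < 4; ++c) nrm[s * 4 + c] = norms_(s, c);
    }
    for (int i = 0; i < N; ++i) {
      if (init[i] < 0 || init[i] >= m) stop("strategy index out of range");
      strat[i] = init[i];
    }
  }

  // one donation round; accumulates into pay/inter/ncoop when counting
  void round(bool counting, std::vector<double>& pay,
             std::vector<long long>& inter, long long& ncoop) {
    int d = (int)(unif_rand() * N); if (d == N) --d;
    int r = (int)(unif_rand() * (N - 1)); if (r == N - 1) --r;
    if (r >= d) ++r;
    int seen = op[(size_t)d * N + r];
    int a = seen ? rul[strat[d] * 2] : rul[strat[d] * 2 + 1];
    if (a == 1 && e_err > 0 && unif_rand() < e_err) a = 0;
    if (counting) {
      if (a == 1) { pay[d] -= cost; pay[r] += benefit; ++ncoop; }
      ++inter[d]; ++inter[r];
    }
    // perception noise is a common shock: all observers see the same
    // (possibly flipped) action, each judging with its own norm
    int pa = a;
    if (a_err > 0 && unif_rand() < a_err) pa = 1 - pa;
    const int base = 2 * pa;
    for (int k = 0; k < N; ++k) {
      int repr = op[(size_t)k * N + r];
      op[(size_t)k * N + d] = nrm[strat[k] * 4 + base + repr];
    }
  }

  void reset_outgoing(int agent) {
    for (int j = 0; j < N; ++j) op[(size_t)agent * N + j] = 1;
  }
};

// Payoff estimation in a fixed population: burn_in unaccounted rounds from
// all-good opinions, then `rounds` accounted rounds.
// [[Rcpp::export]]
List ir_simulate_cpp(IntegerVector strat, IntegerMatrix rules,
                     IntegerMatrix norms, int N, double benefit, double cost,
                     double a_err, double e_err, int rounds, int burn_in) {
  if (strat.size() != N) stop("need one strategy per agent");
  RNGScope scope;
  IrCore core(rules, norms, N, benefit, cost, a_err, e_err, strat);
  std::vector<double> pay(N, 0.0);
  std::vector<long long> inter(N, 0);
  long long ncoop = 0;
  for (int t = 0; t < burn_in; ++t) core.round(false, pay, inter, ncoop);
  for (int t = 0; t < rounds; ++t) core.round(true, pay, inter, ncoop);
  return List::create(_["payoffs"] = NumericVector(pay.begin(), pay.end()),
                      _["interactions"] = IntegerVector(inter.begin(), inter.end()),
                      _["coop"] = (double)ncoop);
}

// Invader/resident payoff vectors by simulation: for each j = 1..N-1, run
// the donation game with j invaders (strategy row 0) and N-j residents
// (row 1) and return the pooled per-interaction payoffs of each type.
// [[Rcpp::export]]
List ir_pair_vectors_cpp(IntegerMatrix rules, IntegerMatrix norms, int N,
                         double benefit, double cost, double a_err,
                         double e_err, int rounds, int burn_in) {
  if (rules.nrow() != 2 || norms.nrow() != 2)
    stop("expected exactly 2 strategies (invader, resident)");
  RNGScope scope;
  NumericVector piI(N - 1), piR(N - 1);
  std::vector<double> pay(N);
  std::vector<long long> inter(N);
  for (int j = 1; j < N; ++j) {
    IntegerVector init(N);
    for (int i = 0; i < N; ++i) init[i] = (i < j) ? 0 : 1;
    IrCore core(rules, norms, N, benefit, cost, a_err, e_err, init);
    std::fill(pay.begin(), pay.end(), 0.0);
    std::fill(inter.begin(), inter.end(), 0);
    long long ncoop = 0;
    for (int t = 0; t < burn_in; ++t) core.round(false, pay, inter, ncoop);
    for (int t = 0; t < rounds; ++t) core.round(true, pay, inter, ncoop);
    double pI = 0, pR = 0; long long nI = 0, nR = 0;
    for (int i = 0; i < N; ++i) {
      if (i < j) { pI += pay[i]; nI += inter[i]; }
      else       { pR += pay[i]; nR += inter[i]; }
    }
    piI[j - 1] = nI > 0 ? pI / (double)nI : 0.0;
    piR[j - 1] = nR > 0 ? pR / (double)nR : 0.0;
  }
  return List::create(_["invader"] = piI, _["resident"] = piR);
}

// Full evolutionary run: windows of rounds_per_step donation rounds
// alternate with single imitation microsteps (focal uniform; exploration mu
// uniform over the m strategies; otherwise role model among the other N-1
// agents with weight exp(beta * per-interaction payoff in the last window)).
// A strategy change resets the agent's outgoing opinions to good.
// [[Rcpp::export]]
List ir_evolve_cpp(IntegerMatrix rules, IntegerMatrix norms, int N,
                   double benefit, double cost, double a_err, double e_err,
                   double beta, double mu, int steps, int burn_in,
                   int rounds_per_step, IntegerVector init) {
  int m = rules.nrow();
  if (norms.nrow() != m) stop("rules and norms must cover the same strategies");
  RNGScope scope;
  IrCore core(rules, norms, N, benefit, cost, a_err, e_err, init);

  std::vector<double> pay(N), pibar(N), w(N);
  std::vector<long long> inter(N);
  std::vector<double> abund(m, 0.0);
  long long coop_num = 0, coop_den = 0, kept = 0;

  for (int step = 1; step <= steps; ++step) {
    std::fill(pay.begin(), pay.end(), 0.0);
    std::fill(inter.begin(), inter.end(), 0);
    long long ncoop = 0;
    for (int t = 0; t < rounds_per_step; ++t)
      core.round(true, pay, inter, ncoop);

    if (step > burn_in) {
      ++kept;
      coop_num += ncoop;
      coop_den += rounds_per_step;
      for (int i = 0; i < N; ++i) abund[core.strat[i]] += 1.0;
    }

    int f = (int)(unif_rand() * N); if (f == N) --f;
    int new_s;
    if (unif_rand() < mu) {
      new_s = (int)(unif_rand() * m); if (new_s == m) --new_s;
    } else {
      double pimax = -1e300;
      for (int k = 0; k < N; ++k) {
        pibar[k] = inter[k] > 0 ? pay[k] / (double)inter[k] : 0.0;
        if (k != f && pibar[k] > pimax) pimax = pibar[k];
      }
      for (int k = 0; k < N; ++k)
        w[k] = (k == f) ? 0.0 : std::exp(beta * (pibar[k] - pimax));
      double tot = 0.0;
      for (int k = 0; k < N; ++k) tot += w[k];
      double u = unif_rand() * tot, acc = 0.0;
      int model = N - 1;
      for (int k = 0; k < N; ++k) {
        acc += w[k];
        if (u < acc) { model = k; break; }
      }
      if (model == f) model = (f + 1) % N;  // unreachable guard
      new_s = core.strat[model];
    }
    if (new_s != core.strat[f]) {
      core.strat[f] = new_s;
      core.reset_outgoing(f);
    }
  }
  NumericVector ab(m);
  for (int s = 0; s < m; ++s) ab[s] = abund[s] / ((double)kept * N);
  return List::create(_["abundances"] = ab,
                      _["coop_index"] = (double)coop_num / (double)coop_den);
}
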