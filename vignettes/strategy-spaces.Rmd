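---
title: "Strategy spaces and the evolution of cooperation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strategy spaces and the evolution of cooperation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopspaces)
```

Evolutionary game models of cooperation are usually built on a handful of
hand-picked strategies. That choice is consequential: with noise and multiple
equilibria, adding or removing strategies that are computationally no more
complex than the ones kept can change which behaviour the model predicts.
`coopspaces` implements the machinery to study this directly — deterministic
and stochastic evolutionary dynamics that are agnostic about the game, plus
three case studies in which small hand-picked strategy spaces are compared
with systematically constructed ones.

This vignette documents the models, the defaults, the numerical choices, and
the places where a genuine design decision had to be made.

## Evolutionary dynamics

**Replicator dynamics.** For strategy frequencies $x$ and payoff matrix $A$,
$\dot x_i = x_i\left[(Ax)_i - x^\top A x\right]$. `integrate_replicator()`
uses classical fixed-step RK4 with the state renormalised onto the simplex
after every step (negative round-off clipped at zero). Fixed stepping was
chosen over adaptive integration for bit-reproducibility; the default step
`dt = 0.01` resolves all the dynamics used here (halving it changes
endpoints by less than $10^{-6}$ in the cases we integrate).

**Imitation process.** A population of $N$ individuals holds one strategy
each. In one microstep a uniformly chosen focal individual either explores
(probability $\mu$): it adopts a strategy drawn uniformly from the *full*
configured set — exploration must be able to reach every computationally
equivalent strategy, which is the point of the exercise — or imitates
(probability $1-\mu$): a role model is drawn from the other $N-1$
individuals with probability proportional to $f = e^{\beta\pi}$, where
$\pi$ is the expected payoff against the current population excluding self
(division by $N-1$, which keeps $N = 2$ well-defined). Because imitation
probabilities depend only on payoff differences, a common offset is
subtracted before exponentiation; this is exact, not an approximation, and
removes any overflow risk. `run_imitation()` reports strategy abundances
*time-averaged* after a burn-in, matching the long-run-average reading of
the quantities of interest, not the modal state.

**Fixation and the small-mutation limit.** For one invader strategy in a
resident population, finite-population payoffs at $j$ invaders are
$\pi_I(j) = \frac{(j-1)a_{II} + (N-j)a_{IR}}{N-1}$, $\pi_R(j) = \frac{j
a_{RI} + (N-j-1)a_{RR}}{N-1}$, and the fixation probability uses the
standard product formula for a birth–death chain whose transition-rate
ratio is $e^{-\beta(\pi_I - \pi_R)}$:
$\rho = \left[1 + \sum_{k=1}^{N-1}\prod_{j=1}^{k}
e^{-\beta(\pi_I(j)-\pi_R(j))}\right]^{-1}$, evaluated in log space.
Neutral invasions return exactly $1/N$. One subtlety: the simulation
microstep excludes the focal individual from the role-model pool, which
perturbs the transition-rate ratio at $O(1/N)$; the product formula ignores
this, as is conventional. The discrepancy is far below the statistical
resolution of any comparison made here, and the equivalence test between
the product formula and an independent absorbing-chain solve is exact
because both use the same ratio.

When exploration is rare the population is almost always monomorphic and
the long run reduces to an $m\times m$ embedded Markov chain over
monomorphic states with off-diagonal entries $\rho(i \leftarrow j)/(m-1)$;
`small_mu_stationary()` returns its unique stationary distribution via a
direct linear solve. For small-mutation reports the cooperation index
weights each strategy by its *self-play* cooperation rate, because the
population spends essentially all its time monomorphic; direct simulation
instead uses opponent-matched rates under the realised composition.

## Case study 1: reactive strategies in the repeated prisoner's dilemma

The stage game has payoffs $(R, S, T, P) = (3, 0, 4, 1)$ by default, with
continuation probability $\delta$ and payoffs normalised by $1-\delta$.
Reactive strategies are triples (first move, reply to C, reply to D); there
are exactly $2^3 = 8$. The three canonical spaces are `pair` = {AllC,
AllD}, `triple` = {AllC, TFT, AllD}, and `full8` (all eight). Deterministic
reactive play is a function of the previous joint move, so every pairing
decomposes into a prefix plus a cycle over at most four joint states;
payoffs and discounted cooperation rates are geometric sums evaluated in
closed form — there is no series truncation anywhere in the package (the
test suite checks the closed forms against a truncated-series oracle with
tail below $10^{-12}$).

An optional per-interaction complexity cost can be attached to any
strategy (canonically to TFT); it is subtracted from the bearer's
normalised payoff in every interaction, the simplest reading of a
complexity cost at the payoff level.

At $\delta = 0.9$ the three-strategy game has exactly two pure symmetric
equilibria (TFT and AllD; weak inequality, so payoff ties admit the
equilibrium — this matters because AllC and TFT tie against TFT). TFT
supports cooperation only for $\delta > (T-R)/(T-P) = 1/3$ at the default
payoffs.

## Case study 2: optional public goods with punishment

Strategies are a participation class — cooperate (C), defect (D), or
abstain as a loner (L) — plus three punishment bits targeting the classes
C, D, L. The full space has $3 \times 2^3 = 24$ strategies; microeconomic
restrictions give the 4-strategy space (only cooperators punish, only
defectors are punished), the 9-strategy space (loners neither punish nor
are punished), and the 12-strategy space (loners cannot be punished but may
punish). Defaults follow the standard parameterisation $r = 3$, $c = 1$,
$\sigma = 1$, fine $= 1$, punishment cost $= 1$, $n = 5$, $N = 100$, with
$0 < \sigma < (r-1)c$ enforced as a warning.

Design decisions worth recording:

* **Sharing rule.** The pool $r c\, n_C$ is divided among the $S$
  participants (the standard optional public-goods model); an
  `others_only` variant (each contribution shared among the *other*
  participants) is available via `pgg_params(sharing = "others_only")`.
* **Punishment only when the game is played** ($S \ge 2$): otherwise no
  actions are observable, and the all-loner state pays exactly $\sigma$.
* **Targeting is by participation class**, including one's own class and
  identical strategies (self excluded); in the 24-strategy space loners
  present in a playing group both punish and are punished.
* **Loner punishers act only when $S \ge 2$** — with at most one
  participant there is nothing to observe.

Expected payoffs in a two-strategy population are exact hypergeometric
expectations over the group composition of the $n-1$ co-players drawn
without replacement from the other $N-1$ individuals, so the embedded
small-mutation chain for this game is deterministic. Monte Carlo group
sampling is retained in `state_payoffs()` for mixed states with more than
two strategies.

## Case study 3: indirect reciprocity with second-order norms

Agents play a donation game (benefit 5, cost 1 by default): the donor
cooperates or not depending on its own opinion of the recipient's binary
reputation. The four action rules (ALLC, DISC, antiDISC, ALLD) combine with
the sixteen second-order social norms — maps (donor action, recipient
reputation) $\to$ reputation — into 64 strategies. The `exogenous` space
fixes one norm for everyone (stern judging by default: cooperating with the
good and defecting against the bad are good; the opposite are bad) and lets
only the 4 action rules evolve; the `endogenous` space evolves all 64
combinations.

Opinions are *private*: every agent holds an opinion of every other agent,
and after each interaction every agent — including the donor judging itself
with its own norm — updates its opinion of the donor by applying its norm
to the perceived action and its *own* opinion of the recipient. Privacy is
the only coherent bookkeeping once norms are heterogeneous, and it makes
the neutrality of an unconditional agent's norm literally true: swapping
the norm of an ALLC or ALLD agent changes nothing observable, which the
test suite verifies by coupling two runs on an identical random stream.

Two related design decisions:

* **Assessment noise is a common perception shock.** With probability
  `assess_error` the *action* is misperceived, identically for every
  observer, rather than each observer flipping its conclusion
  independently. Independent per-observer noise makes privately held
  opinions decorrelate — stern judging then famously fails to sustain
  discriminator cooperation — whereas the phenomena studied here concern
  the strategy space, not information fragmentation. With a common shock,
  an error-free population sharing one norm recovers the public-reputation
  limit exactly (all opinion columns agree), which is also a tested
  invariant.
* **The donor judges itself.** Without self-judgment the recipient's view
  of its own reputation could never update, silently breaking the public
  limit above. Self-judgment uses the donor's own norm and the same
  perceived action.

An agent whose strategy changes resets its outgoing opinions to "good";
others' opinions of it persist.

Two long-run computations are exposed, mirroring the two standard
methodologies. `ir_evolve()` is the direct agent-based process:
reputations evolve continuously, and after every window of `10 N` donation
rounds one imitation microstep uses the window's per-interaction average
payoffs. Averaging per interaction (rather than per round) keeps the payoff
scale — and therefore the meaning of $\beta$ — independent of $N$;
`ir_estimate_payoffs()` reports both. `ir_small_mu()` is the embedded
small-mutation chain with invader/resident payoff vectors estimated by
simulating the reputation dynamics at every mixed composition ($1000$
accounted rounds after $300$ equilibration rounds per composition, pooled
per type). The chain is the right tool for long-run comparisons across
spaces: the direct process at $N = 50$ sits for very long stretches in
single-strategy basins (the escape from unconditional defection requires a
multi-mutant excursion), so matching its mixing time is computationally
far more expensive than integrating the transitions exactly.

## Experiments, seeds and reproducibility

`run_experiment()` executes (grid point × strategy set × replicate) cells
with per-cell seeds derived from a master seed by a stable 31-bit hash, so
any cell can be re-run in isolation and whole tables reproduce
byte-for-byte. Configurations round-trip through YAML. Replicates (default
intent: ~10 with mean ± standard error) are this package's addition for
uncertainty quantification; the classical presentations show single long
runs.

Problem sizes used by the shipped tests and the acceptance script — $2
\times 10^6$ imitation microsteps for the repeated-game simulations, 5–10
replicates per condition, and the pairwise simulation effort quoted above
for the norm chains — were chosen so that replicate standard errors are an
order of magnitude below the effects being examined.

## What the synthetic dynamics do and do not show

All data in this package are generated by the models themselves; nothing is
fitted to empirical observations. Passing tests therefore demonstrate
internal consistency (closed forms against independent oracles, simulation
against exact limits) and the qualitative robustness claims about strategy
spaces — they do not validate the models against behavioural data. Known
limitations, deliberately out of scope: structured populations,
pairwise-comparison and Wright–Fisher updates, stochastic or longer-memory
repeated-game strategies, pool punishment and second-order punishment,
continuous or third-order reputations, and observation models where only
subsets of agents witness an interaction (the full-observation choice here
speeds opinion mixing at $N = 50$; a sampling-observer variant would slow
reputation spread and weaken discrimination).

## A worked comparison

```{r example, eval = FALSE}
# cooperation across punishment strategy spaces (exact small-mutation chain)
p <- pgg_params()
sapply(c("four", "nine", "twelve", "full24"), function(restr) {
  space <- pgg_strategy_space(restr)
  small_mu_stationary(pgg_oracle(space, p), p$N, beta = 1,
                      coop = pgg_coop_fraction(space))$cooperation_index
})
#>      four      nine    twelve    full24
#> 0.9128417 0.9128417 0.6263432 0.3810436
```

The 4- and 9-strategy restrictions agree to six decimals — restricting
antisocial punishment *by loners only* leaves the classical prediction
intact — while freeing every punishment channel collapses cooperation by
more than half. Which restriction is right is not a mathematical question:
it depends on whether the situation being modelled lets non-participants
observe, sanction, and be sanctioned.
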