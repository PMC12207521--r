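# coopspaces

Evolutionary game dynamics for studying how the **choice of strategy space**
shapes predictions about the evolution of cooperation.

Models of cooperation are usually analysed with a few hand-picked strategies
(AllC, TFT, AllD; cooperators, defectors, punishers; ...). With noise and
multiple equilibria, that choice can drive the outcome: a model may predict
thriving cooperation simply because the strategies that would undermine it —
computationally no more complex than the ones kept — were never put in.
`coopspaces` provides game-agnostic deterministic and stochastic evolutionary
dynamics plus three classical case studies in which small hand-picked spaces
are compared against systematically constructed ones. It is aimed at
researchers in evolutionary game theory, social evolution, and multi-agent
systems who want strategy-space robustness checks to be routine.

## Models

**Dynamics** (module `R/replicator.R`, `R/imitation.R`, `R/fixation.R`):

- Replicator dynamics `dx_i/dt = x_i[(Ax)_i − xᵀAx]`, integrated with
  fixed-step RK4 on the simplex.
- A finite-population imitation process: a random focal individual either
  explores (probability μ, uniform over the full strategy set) or imitates a
  role model drawn from the other N−1 individuals with probability
  ∝ exp(β·payoff); payoffs exclude self-interaction.
- Exact fixation probabilities
  ρ = [1 + Σₖ Πⱼ exp(−β(π_I(j) − π_R(j)))]⁻¹ and the small-mutation-limit
  embedded chain over monomorphic states, whose stationary distribution gives
  long-run strategy abundances and a cooperation index.

**Case studies:**

1. *Repeated prisoner's dilemma* (`R/repeated_pd.R`) — all 8 reactive
   (memory-1, opponent-conditioned) strategies, with exact closed-form
   discounted payoffs via the prefix/cycle decomposition of deterministic
   play; strategy sets `pair`, `triple`, `full8`; optional complexity costs.
2. *Optional public goods with punishment* (`R/optional_pgg.R`) — strategies
   are a participation class (C/D/loner) × punishment bits per target class;
   restrictions of 4/9/12/24 strategies encode different microeconomic
   assumptions about who can punish whom; exact hypergeometric expected
   payoffs.
3. *Indirect reciprocity* (`R/indirect_recip.R`) — 4 action rules × 16
   second-order social norms; private reputations; exogenous (fixed stern
   judging, 4 strategies) vs endogenous (64 strategies) norm spaces.

An experiment runner (`R/experiments.R`) orchestrates seeded sweeps with
YAML configs, and `inst/cli/coopspaces-cli.R` is a thin command-line front
end.

## Worked example

Cooperation across the four punishment strategy spaces, via the exact
small-mutation chain at the standard parameters (r = 3, c = 1, σ = 1,
fine = cost = 1, group size 5, N = 100, β = 1):

```r
library(coopspaces)
p <- pgg_params()
sapply(c("four", "nine", "twelve", "full24"), function(restr) {
  space <- pgg_strategy_space(restr)
  small_mu_stationary(pgg_oracle(space, p), p$N, beta = 1,
                      coop = pgg_coop_fraction(space))$cooperation_index
})
#>      four      nine    twelve    full24
#> 0.9128417 0.9128417 0.6263432 0.3810436
```

The hand-picked 4-strategy space and the 9-strategy space (loners neither
punish nor are punished) agree to six decimals: cooperation, carried by the
pro-social punisher, is robust to *that* extension. Allowing everyone to
punish and be punished (24 strategies) collapses cooperation to 0.38 — the
prediction hinges on a microeconomic assumption, not on the mechanism.

The same exercise for the repeated game:

```r
g <- pd_payoff_matrix(pd_strategy_set("triple"), pd_params(delta = 0.9))
small_mu_stationary(pairwise_oracle(g$payoff), N = 20, beta = 5,
                    coop = g$self_coop)
#> <stationary_report> method = small_mu  cooperation_index = 0.7609
#> top strategies:
#>   TFT          0.7262
#>   AllD         0.2391
#>   AllC         0.0347
```

TFT and AllD — the two pure equilibria of the three-strategy game — dominate
the long run; the cooperation index is their abundance-weighted self-play
cooperation.

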