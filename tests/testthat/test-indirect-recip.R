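test_that("stern judging has its canonical truth table", {
  sj <- stern_judging()
  expect_equal(sj$CG, "G")  # cooperating with the good is good
  expect_equal(sj$DG, "B")  # defecting on the good is bad
  expect_equal(sj$CB, "B")  # helping the bad is bad
  expect_equal(sj$DB, "G")  # punishing the bad is good
  # flipping the action flips the judgement, at either reputation
  expect_false(sj$CG == sj$DG)
  expect_false(sj$CB == sj$DB)
  # flipping the recipient's reputation also flips the judgement
  expect_false(sj$CG == sj$CB)
  expect_false(sj$DG == sj$DB)
})

test_that("rule and norm spaces have the right cardinalities", {
  expect_equal(nrow(action_rules()), 4)
  norms <- social_norms()
  expect_equal(nrow(norms), 16)
  expect_equal(length(unique(norms$label)), 16)
  expect_true(stern_judging()$label %in% norms$label)
  exo <- ir_strategy_space("exogenous")
  endo <- ir_strategy_space("endogenous")
  expect_equal(nrow(exo), 4)
  expect_equal(nrow(endo), 64)
  expect_equal(length(unique(endo$label)), 64)
  # every exogenous strategy carries the fixed norm
  expect_true(all(exo$norm == stern_judging()$label))
})

test_that("a donation round transfers payoffs and updates opinions", {
  sp <- ir_strategy_space("exogenous")
  p <- ir_params(N = 6, assess_error = 0, exec_error = 0)
  # unconditional defectors never cooperate
  st <- ir_state(rep("ALLD", 6), sp)
  set.seed(31)
  for (i in 1:20) {
    st <- interaction_round(st, p)
    expect_equal(st$last$action, "D")
  }
  expect_true(all(st$payoffs == 0))
  # realised cooperation moves exactly benefit - cost in aggregate
  st <- ir_state(rep("ALLC", 6), sp)
  set.seed(8)
  st <- interaction_round(st, p)
  expect_equal(st$last$action, "C")
  expect_equal(sum(st$payoffs), p$benefit - p$cost)
  expect_equal(min(st$payoffs), -p$cost)
  # a stern-judging population marks a defector against a good recipient bad
  st <- ir_state(rep("ALLD", 6), sp)  # opinions all good initially
  set.seed(31)
  st <- interaction_round(st, p)
  expect_true(all(st$opinions[, st$last$donor] == 0L))
  expect_true(all(st$opinions %in% c(0L, 1L)))
})

test_that("an unconditional agent's norm never feeds back into play", {
  # swap the norm of an ALLD agent: with an identical random stream the
  # entire trajectory of actions and payoffs must be bit-identical
  endo <- ir_strategy_space("endogenous")
  p <- ir_params(N = 8, assess_error = 0.05, exec_error = 0.05)
  pop1 <- c("ALLD.NGBBG", rep("DISC.NGBBG", 4), rep("ALLC.NGBBG", 3))
  pop2 <- pop1
  pop2[1] <- "ALLD.NBGGB"  # same rule, very different norm
  run_traj <- function(pop) {
    st <- ir_state(pop, endo)
    set.seed(2024)
    acts <- character(300)
    for (i in 1:300) {
      st <- interaction_round(st, p)
      acts[i] <- paste(st$last$donor, st$last$recipient, st$last$action)
    }
    list(acts = acts, payoffs = st$payoffs)
  }
  t1 <- run_traj(pop1)
  t2 <- run_traj(pop2)
  expect_identical(t1$acts, t2$acts)
  expect_identical(t1$payoffs, t2$payoffs)
})

test_that("without errors a shared norm recovers public information", {
  # heterogeneous rules, one norm, no noise: all observers agree about
  # everyone at all times (opinion columns are constant)
  sp <- ir_strategy_space("exogenous")
  p <- ir_params(N = 8, assess_error = 0, exec_error = 0)
  st <- ir_state(rep(c("DISC", "ALLD", "ALLC", "antiDISC"), 2), sp)
  set.seed(5)
  for (i in 1:200) st <- interaction_round(st, p)
  for (j in 1:8) {
    expect_equal(length(unique(st$opinions[, j])), 1L)
  }
})

test_that("payoff estimation matches unconditional baselines", {
  sp <- ir_strategy_space("exogenous")
  p <- ir_params(N = 20, exec_error = 0, assess_error = 0.01)
  set.seed(1)
  expect_equal(ir_estimate_payoffs(rep("ALLC", 20), sp, p, rounds = 2000)$coop_rate, 1)
  set.seed(1)
  expect_equal(ir_estimate_payoffs(rep("ALLD", 20), sp, p, rounds = 2000)$coop_rate, 0)
  # discriminators under stern judging sustain near-full cooperation
  set.seed(1)
  disc <- ir_estimate_payoffs(rep("DISC", 20), sp, ir_params(N = 20), rounds = 5000)
  expect_gt(disc$coop_rate, 0.9)
})

test_that("norm variants of unconditional defectors earn identical payoffs", {
  endo <- ir_strategy_space("endogenous")
  p <- ir_params(N = 10)
  pop <- c(rep("ALLD.NGBBG", 5), rep("ALLD.NBGGB", 5))
  set.seed(77)
  r <- ir_estimate_payoffs(pop, endo, p, rounds = 5000)
  # same rule, different norm: payoff distributions coincide; with a shared
  # stream the realised per-round payoffs are statistically indistinguishable
  expect_equal(mean(r$payoff_per_round[1:5]), mean(r$payoff_per_round[6:10]),
               tolerance = 0.05)
  expect_equal(r$coop_rate, 0)
})

test_that("evolution over norm spaces is seeded and reproducible", {
  p <- ir_params(N = 20)
  ev <- evo_params(N = 20, beta = 1, mu = 0.01, steps = 2000, burn_in = 500,
                   seed = 12)
  r1 <- ir_evolve("exogenous", p, ev, rounds_per_step = 100)
  r2 <- ir_evolve("exogenous", p, ev, rounds_per_step = 100)
  expect_identical(r1$abundances, r2$abundances)
  expect_identical(r1$cooperation_index, r2$cooperation_index)
  expect_equal(length(r1$abundances), 4)
  expect_equal(sum(r1$abundances), 1, tolerance = 1e-9)
  expect_error(ir_evolve("exogenous", p, evo_params(N = 30, steps = 100,
                                                    burn_in = 10)), "equal")
})

test_that("the embedded chain over norm strategies is reproducible", {
  p <- ir_params(N = 16)
  r1 <- ir_small_mu("exogenous", p, beta = 1, seed = 4,
                    rounds = 200, burn_in = 100, coop_rounds = 500)
  r2 <- ir_small_mu("exogenous", p, beta = 1, seed = 4,
                    rounds = 200, burn_in = 100, coop_rounds = 500)
  expect_identical(r1$abundances, r2$abundances)
  expect_equal(sum(r1$abundances), 1, tolerance = 1e-9)
  expect_true(r1$cooperation_index >= 0 && r1$cooperation_index <= 1)
})

test_that("parameter validation rejects degenerate donation games", {
  expect_error(ir_params(benefit = 1, cost = 2), "benefit > cost")
  expect_error(ir_params(assess_error = 0.6), "assess_error")
  expect_error(ir_state("DISCO", ir_strategy_space("exogenous")), "unknown")
})
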