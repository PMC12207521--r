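test_that("replicator right-hand side matches the excess-payoff formula", {
  # monomorphic states are fixed points
  expect_equal(replicator_rhs(c(1, 0), matrix(c(1, 2, 3, 4), 2)), c(0, 0))
  # equal payoffs imply neutrality
  expect_equal(replicator_rhs(c(0.5, 0.5), matrix(5, 2, 2)), c(0, 0))
  # one-shot PD: defection grows at the expense of cooperation
  A <- matrix(c(3, 4, 0, 1), 2, 2)  # rows: C, D; cols: C, D
  dx <- replicator_rhs(c(0.5, 0.5), A)
  expect_gt(dx[2], 0)
  expect_lt(dx[1], 0)
  expect_error(replicator_rhs(c(0.5, 0.5), matrix(1, 3, 3)), "mismatch")
  expect_error(replicator_rhs(c(0.7, 0.7), diag(2)), "simplex")
})

test_that("replicator components sum to zero on random games", {
  games <- fixture_games(seed = 404, n_games = 12)
  set.seed(1)
  for (g in games) {
    m <- nrow(g$A)
    x <- runif(m)
    x <- x / sum(x)
    expect_lt(abs(sum(replicator_rhs(x, g$A))), 1e-12)
  }
})

test_that("replicator integration reproduces known trajectories", {
  # 2-strategy PD: pi_C - pi_D = -1 everywhere, so x_C decays logistically
  A <- matrix(c(3, 4, 0, 1), 2, 2)
  traj <- integrate_replicator(c(0.9, 0.1), A, t_end = 5, dt = 0.005)
  ts <- c(1, 2.5, 5)
  for (t in ts) {
    idx <- which.min(abs(traj$times - t))
    expect_equal(traj$states[idx, 1], replicator_logistic(0.9, -1, traj$times[idx]),
                 tolerance = 1e-6)
  }
  # AllD corner of the three-strategy repeated game is locally attracting
  g <- pd_payoff_matrix(pd_strategy_set("triple"), fig1_pd())
  tr <- integrate_replicator(c(0.05, 0.05, 0.9), g$payoff, t_end = 150)
  expect_gt(tr$states[nrow(tr$states), 3], 0.999)
  # a pure population is a fixed point
  tr2 <- integrate_replicator(c(0, 1, 0), g$payoff, t_end = 2)
  expect_equal(tr2$states[nrow(tr2$states), ], c(AllC = 0, TFT = 1, AllD = 0))
})

test_that("exponential fitness mapping behaves like exp(beta * payoff)", {
  expect_equal(exp_fitness(0, 1), 1)
  expect_equal(exp_fitness(2, 0), 1)
  # fitness ratios depend only on payoff differences, offset is exact
  expect_equal(exp_fitness(3, 2, offset = 7) / exp_fitness(1, 2, offset = 7),
               exp(2 * (3 - 1)))
  expect_error(exp_fitness(1, -1), "beta")
})

test_that("imitation microstep conserves the population and explores uniformly", {
  A <- matrix(c(3, 4, 0, 1), 2, 2)
  oracle <- pairwise_oracle(A, c("C", "D"))
  params <- evo_params(N = 10, beta = 1, mu = 0, steps = 10, burn_in = 0, seed = 1)
  set.seed(42)
  counts <- c(5L, 5L)
  for (i in 1:200) {
    counts <- imitation_step(counts, oracle, params)
    expect_equal(sum(counts), 10)
    expect_true(all(counts >= 0))
  }
  # mu = 1: the adopted strategy is uniform over the whole set
  o3 <- pairwise_oracle(matrix(0, 3, 3))
  pm <- evo_params(N = 9, beta = 1, mu = 1, steps = 10, burn_in = 0, seed = 1)
  set.seed(7)
  start <- c(9L, 0L, 0L)
  adopted <- integer(3)
  for (i in 1:3000) {
    delta <- imitation_step(start, o3, pm) - start
    s <- if (all(delta == 0)) 1L else which(delta == 1L)
    adopted[s] <- adopted[s] + 1L
  }
  expect_true(all(abs(adopted / 3000 - 1 / 3) < 0.05))
})

test_that("evo_params validates its invariants", {
  expect_error(evo_params(N = 1), "N")
  expect_error(evo_params(mu = 1.5), "mu")
  expect_error(evo_params(steps = 100, burn_in = 100), "burn_in")
})

test_that("fixation probability has the right limits and closed forms", {
  A <- matrix(c(2, 5, 1, 3), 2, 2)
  # neutral drift fixes at exactly 1/N
  for (N in c(2, 5, 11)) {
    expect_identical(fixation_probability_game(A, N, beta = 0), 1 / N)
  }
  # N = 2: single-term sum
  v <- pair_payoff_vectors(pairwise_oracle(A), 1, 2, 2)
  beta <- 0.7
  expect_equal(fixation_probability(v$invader, v$resident, beta),
               1 / (1 + exp(-beta * (v$invader - v$resident))))
  expect_error(fixation_probability(1, numeric(0), 1), "length")
})

test_that("small-mutation chain recovers symmetry and known equilibria", {
  # all payoffs equal: uniform over any number of strategies
  for (m in c(2, 5)) {
    r <- small_mu_stationary(pairwise_oracle(matrix(1, m, m)), N = 20, beta = 2)
    expect_equal(unname(r$abundances), rep(1 / m, m), tolerance = 1e-12)
  }
  # strong selection in the three-strategy repeated game: the two equilibria
  # TFT and AllD are the most abundant strategies
  g <- pd_payoff_matrix(pd_strategy_set("triple"), fig1_pd())
  r <- small_mu_stationary(pairwise_oracle(g$payoff), N = 20, beta = 5,
                           coop = g$self_coop)
  top2 <- names(sort(r$abundances, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("TFT", "AllD"))
  expect_true(r$cooperation_index >= 0 && r$cooperation_index <= 1)
})

test_that("simulated abundances converge to the embedded-chain limit", {
  # 2-strategy game, rare exploration: time averages should approach the
  # small-mutation stationary distribution
  A <- matrix(c(1, 1.4, 1.4, 1), 2, 2)  # coexistence-flavoured game
  oracle <- pairwise_oracle(A, c("X", "Y"))
  chain <- small_mu_stationary(oracle, N = 16, beta = 0.3)
  sims <- vapply(1:6, function(r) {
    p <- evo_params(N = 16, beta = 0.3, mu = 1e-3, steps = 1e6,
                    burn_in = 1e5, seed = 100 + r)
    run_imitation(oracle, p)$abundances[1]
  }, numeric(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - chain$abundances[1]), 3 * se + 0.02)
})

test_that("identical seeds give bit-identical reports", {
  g <- pd_payoff_matrix(pd_strategy_set("triple"), fig1_pd())
  p <- evo_params(N = 20, beta = 1, mu = 1e-3, steps = 5e4, burn_in = 5e3, seed = 99)
  r1 <- run_imitation(pairwise_oracle(g$payoff), p, coop = g$coop)
  r2 <- run_imitation(pairwise_oracle(g$payoff), p, coop = g$coop)
  expect_identical(r1$abundances, r2$abundances)
  expect_identical(r1$cooperation_index, r2$cooperation_index)
})

test_that("absorbing dynamics without exploration stay monomorphic", {
  g <- pd_payoff_matrix(pd_strategy_set("triple"), fig1_pd())
  p <- evo_params(N = 20, beta = 1, mu = 0, steps = 2e4, burn_in = 2e3, seed = 3)
  r <- run_imitation(pairwise_oracle(g$payoff), p, coop = g$coop,
                     init = c(0L, 0L, 20L))
  expect_equal(unname(r$abundances), c(0, 0, 1))
  expect_equal(r$cooperation_index, 0)
})

test_that("stationary reports validate and serialise", {
  expect_error(stationary_report(c(a = 0.6, b = 0.6)), "sum to 1")
  rep_obj <- stationary_report(c(a = 0.25, b = 0.75), 0.4, method = "small_mu",
                               params = list(N = 10, seed = 1))
  tmp <- tempfile()
  paths <- write_report(rep_obj, tmp)
  got <- read.csv(paths[["csv"]])
  expect_equal(got$abundance, c(0.25, 0.75))
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$cooperation_index, 0.4)
  expect_equal(meta$params$N, 10)
})
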