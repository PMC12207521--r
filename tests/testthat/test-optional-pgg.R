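test_that("restricted strategy spaces have the right membership", {
  four <- pgg_strategy_space("four")
  nine <- pgg_strategy_space("nine")
  twelve <- pgg_strategy_space("twelve")
  full <- pgg_strategy_space("full24")
  expect_equal(nrow(four), 4)
  expect_equal(nrow(nine), 9)
  expect_equal(nrow(twelve), 12)
  expect_equal(nrow(full), 24)
  expect_equal(length(unique(full$label)), 24)
  # nesting: four within twelve within full24; nine not within twelve
  expect_true(all(four$label %in% twelve$label))
  expect_true(all(twelve$label %in% full$label))
  expect_true(all(nine$label %in% full$label))
  # the antisocial punisher (a defector punishing cooperators) exists at 9
  expect_true("D:pC" %in% nine$label)
  # no strategy in the 4-set punishes cooperators or loners
  expect_false(any(four$punish_C | four$punish_L))
  # loners never punish in the 9-set but may punish in the 12-set
  expect_false(any(nine$punish_C[nine$participation == "L"]))
  expect_true(any(twelve$participation == "L" &
                  (twelve$punish_C | twelve$punish_D)))
  # loners are never punished below 24 strategies
  expect_false(any(nine$punish_L) || any(twelve$punish_L))
  expect_error(pgg_strategy_space("six"), "four, nine, twelve, full24")
})

test_that("group payoffs follow the two-stage game", {
  p <- pgg_params(r = 3, c = 1, sigma = 1, fine = 1, cost_pun = 1, n = 5, N = 100)
  allL <- do.call(rbind, replicate(5, pgg_strategy("L"), simplify = FALSE))
  expect_equal(pgg_group_payoffs(allL, p), rep(1, 5))
  allC <- do.call(rbind, replicate(5, pgg_strategy("C"), simplify = FALSE))
  expect_equal(pgg_group_payoffs(allC, p), rep(2, 5))  # (r - 1) c
  # a lone participant cannot play: everyone gets sigma
  oneC <- rbind(pgg_strategy("C", punish_D = TRUE),
                do.call(rbind, replicate(4, pgg_strategy("L"), simplify = FALSE)))
  expect_equal(pgg_group_payoffs(oneC, p), rep(1, 5))
  # punisher among defectors and a loner (hand-enumerated)
  grp <- rbind(pgg_strategy("C", punish_D = TRUE), pgg_strategy("D"),
               pgg_strategy("D"), pgg_strategy("D"), pgg_strategy("L"))
  expect_equal(pgg_group_payoffs(grp, p), c(-3.25, -0.25, -0.25, -0.25, 1))
  expect_error(pgg_group_payoffs(grp[1:4, ], p), "group size")
})

test_that("punishment respects the fine/cost budget identity", {
  p <- pgg_params(fine = 1.7, cost_pun = 0.6, n = 6, N = 50)
  space <- pgg_strategy_space("full24")
  set.seed(21)
  for (rep_i in 1:20) {
    idx <- sample.int(24, 6, replace = TRUE)
    grp <- space[idx, , drop = FALSE]
    cls <- grp$participation
    S <- sum(cls != "L")
    pay <- pgg_group_payoffs(grp, p)
    # baseline: same group with all punishment bits cleared
    plain <- grp
    plain$punish_C <- plain$punish_D <- plain$punish_L <- FALSE
    base <- pgg_group_payoffs(plain, p)
    n_pairs <- 0
    if (S >= 2) {
      cnt <- table(factor(cls, levels = c("C", "D", "L")))
      bits <- as.matrix(grp[, c("punish_C", "punish_D", "punish_L")])
      for (i in 1:6) {
        targets <- cnt - (c("C", "D", "L") == cls[i])
        n_pairs <- n_pairs + sum(bits[i, ] * targets)
      }
    }
    expect_equal(sum(base) - sum(pay), n_pairs * (p$fine + p$cost_pun))
  }
})

test_that("exact expected payoffs agree with degenerate and sampled cases", {
  p <- pgg_params(n = 5, N = 30)
  A <- pgg_strategy("C", punish_D = TRUE)
  B <- pgg_strategy("D", punish_C = TRUE)
  # identical strategies earn identically at every composition
  for (j in c(1, 15, 29)) {
    v <- pgg_expected_payoffs(A, A, j, p)
    expect_equal(v[["A"]], v[["B"]])
  }
  # N = n: the whole population forms the single group
  pn <- pgg_params(n = 5, N = 5)
  v <- pgg_expected_payoffs(A, B, 2, pn)
  grp <- rbind(A, A, B, B, B)
  direct <- pgg_group_payoffs(grp, pn)
  expect_equal(v[["A"]], direct[1])
  expect_equal(v[["B"]], direct[3])
  # Monte Carlo group sampling reproduces the hypergeometric expectation
  set.seed(9)
  j <- 12
  draws <- replicate(4000, {
    others <- c(rep(1, j - 1), rep(2, p$N - j))
    co <- sample(others, p$n - 1)
    grp <- rbind(A, A[rep(1, sum(co == 1)), , drop = FALSE],
                 B[rep(1, sum(co == 2)), , drop = FALSE])
    pgg_group_payoffs(grp, p)[1]
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - pgg_expected_payoffs(A, B, j, p)[["A"]]), 3 * se)
})

test_that("oracle payoff vectors match the per-composition expectations", {
  p <- pgg_params(n = 5, N = 20)
  space <- pgg_strategy_space("four")
  oracle <- pgg_oracle(space, p)
  v <- pair_payoff_vectors(oracle, 4, 2, 20)  # punisher invading defectors
  for (j in c(1, 7, 19)) {
    e <- pgg_expected_payoffs(space[4, ], space[2, ], j, p)
    expect_equal(v$invader[j], e[["A"]])
    expect_equal(v$resident[j], e[["B"]])
  }
})

test_that("cooperation indicator depends only on the participation class", {
  space <- pgg_strategy_space("full24")
  cf <- pgg_coop_fraction(space)
  expect_equal(cf, as.numeric(space$participation == "C"))
  expect_equal(sum(cf), 8)
})

test_that("neutral selection makes every restriction uniform", {
  p <- pgg_params()
  for (restr in c("four", "twelve")) {
    space <- pgg_strategy_space(restr)
    r <- small_mu_stationary(pgg_oracle(space, p), p$N, beta = 0)
    expect_equal(unname(r$abundances), rep(1 / nrow(space), nrow(space)),
                 tolerance = 1e-12)
  }
})

test_that("parameter validation flags degenerate loner payoffs", {
  expect_warning(pgg_params(sigma = 5), "sigma")
  expect_error(pgg_params(n = 1), "group size")
  expect_error(pgg_params(n = 10, N = 5), "group size")
})
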