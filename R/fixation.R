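# Fixation probabilities and the small-mutation-limit embedded chain.

#' Fixation probability of a single invader
#'
#' For an invader strategy in a resident population of size N, with expected
#' payoffs `pi_invader[j]` / `pi_resident[j]` when there are j invaders,
#' the birth-death chain with transition-rate ratio
#' `T-/T+ = exp(-beta * (pi_invader - pi_resident))` has fixation probability
#' `rho = 1 / (1 + sum_{k=1}^{N-1} prod_{j=1}^{k} exp(-beta (pi_I(j) - pi_R(j))))`.
#' Computed in log space; at `beta = 0` this is exactly `1/N`.
#'
#' @param pi_invader,pi_resident numeric vectors of length `N - 1`.
#' @param beta selection intensity (>= 0).
#' @return fixation probability in `(0, 1)`.
#' @export
fixation_probability <- function(pi_invader, pi_resident, beta) {
  if (length(pi_invader) != length(pi_resident) || length(pi_invader) < 1) {
    stop("payoff vectors must have equal length N - 1 >= 1 (so N >= 2)")
  }
  if (beta < 0) stop("beta must be >= 0")
  L <- cumsum(-beta * (pi_invader - pi_resident))
  # neutral invasions (beta = 0 or identical payoffs) fix at exactly 1/N
  if (all(L == 0)) return(1 / (length(L) + 1))
  # rho = 1 / (1 + sum(exp(L))), stabilised against overflow
  M <- max(0, L)
  denom_log <- M + log(exp(-M) + sum(exp(L - M)))
  exp(-denom_log)
}

#' Fixation probability in a 2x2 matrix game
#'
#' Convenience wrapper building finite-population payoff vectors
#' (self-interaction excluded) from a pairwise game.
#'
#' @param A square payoff matrix (at least 2 x 2).
#' @param N population size (>= 2).
#' @param beta selection intensity.
#' @param invader,resident strategy indices into `A`.
#' @return fixation probability.
#' @export
fixation_probability_game <- function(A, N, beta, invader = 1L, resident = 2L) {
  if (N < 2) stop("N must be >= 2")
  v <- pair_payoff_vectors(pairwise_oracle(A), invader, resident, N)
  fixation_probability(v$invader, v$resident, beta)
}

#' Stationary distribution in the small-mutation limit
#'
#' In the rare-mutation regime the population is almost always monomorphic
#' and long-run behaviour reduces to an embedded Markov chain over the m
#' monomorphic states: a mutant of strategy i appears in a resident-j
#' population with probability 1/(m-1) and fixes with probability
#' `rho(i <- j)`. Returns the chain's unique stationary distribution.
#'
#' @param oracle a payoff oracle (any class providing [pair_payoff_vectors()]).
#' @param N population size.
#' @param beta selection intensity.
#' @param coop optional length-m vector of per-strategy cooperation rates in
#'   the monomorphic state; the cooperation index is their abundance-weighted
#'   mean.
#' @param params extra metadata recorded in the report.
#' @return a [stationary_report()] with `method = "small_mu"`.
#' @export
small_mu_stationary <- function(oracle, N, beta, coop = NULL, params = list()) {
  m <- n_strategies(oracle)
  if (m < 2) stop("need at least 2 strategies")
  P <- matrix(0, m, m)
  for (res in seq_len(m)) {
    for (inv in seq_len(m)) {
      if (inv == res) next
      v <- pair_payoff_vectors(oracle, inv, res, N)
      P[res, inv] <- fixation_probability(v$invader, v$resident, beta) / (m - 1)
    }
  }
  diag(P) <- 1 - rowSums(P)
  ab <- .stationary_distribution(P)
  names(ab) <- strategy_labels(oracle)
  ci <- NA_real_
  if (!is.null(coop)) {
    stopifnot(length(coop) == m)
    ci <- sum(ab * coop)
  }
  stationary_report(ab, cooperation_index = ci, method = "small_mu",
                    params = c(params, list(N = N, beta = beta)))
}

# left null vector of P - I with sum-to-one constraint
.stationary_distribution <- function(P) {
  m <- nrow(P)
  M <- t(P) - diag(m)
  M[m, ] <- 1
  b <- c(rep(0, m - 1), 1)
  pi <- tryCatch(solve(M, b), error = function(e) {
    stop("stationary distribution solve failed (singular chain?): ",
         conditionMessage(e))
  })
  pi <- pmax(pi, 0)
  pi / sum(pi)
}
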