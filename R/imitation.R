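# Stochastic imitation dynamics in a finite population.
#
# Microstep: a uniformly chosen focal individual either explores (probability
# mu: adopts a strategy drawn uniformly from the full configured set) or
# imitates a role model drawn from the other N - 1 individuals with
# probability proportional to exp(beta * payoff). Payoffs are computed against
# the current population excluding self.

#' Exponential payoff-to-fitness mapping
#'
#' `f = exp(beta * payoff)`. Since imitation probabilities depend only on
#' payoff differences, a common `offset` may be subtracted before
#' exponentiation to avoid overflow; this is exact, not an approximation.
#'
#' @param payoff numeric payoff(s).
#' @param beta selection intensity (>= 0; 0 is neutral drift).
#' @param offset common payoff offset subtracted before exponentiation.
#' @return numeric fitness value(s).
#' @export
exp_fitness <- function(payoff, beta, offset = 0) {
  if (beta < 0) stop("beta must be >= 0")
  z <- beta * (payoff - offset)
  z <- pmin(z, 700)  # guard: callers should centre payoffs via offset
  exp(z)
}

#' Parameters of the stochastic evolutionary process
#'
#' @param N population size (integer >= 2).
#' @param beta selection intensity (>= 0).
#' @param mu exploration (mutation) probability in `[0, 1]`.
#' @param steps number of imitation microsteps.
#' @param burn_in microsteps discarded before averaging (`< steps`).
#' @param seed RNG seed (integer).
#' @return object of class `evo_params`.
#' @export
evo_params <- function(N = 20L, beta = 1, mu = 1e-3, steps = 2e6,
                       burn_in = floor(steps / 10), seed = 1L) {
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  steps <- as.integer(steps)
  burn_in <- as.integer(burn_in)
  if (burn_in >= steps) stop("burn_in must be < steps")
  if (burn_in < 0) stop("burn_in must be >= 0")
  structure(list(N = N, beta = beta, mu = mu, steps = steps,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "evo_params")
}

#' @export
print.evo_params <- function(x, ...) {
  cat("<evo_params> N =", x$N, " beta =", x$beta, " mu =", x$mu,
      " steps =", x$steps, " burn_in =", x$burn_in, " seed =", x$seed, "\n")
  invisible(x)
}

#' One imitation microstep
#'
#' Uses the current R random number stream; call `set.seed()` for
#' reproducibility. Total population count is conserved.
#'
#' @param counts integer vector of strategy counts summing to `params$N`.
#' @param oracle a payoff oracle covering all strategies in the configured set.
#' @param params an [evo_params()] object.
#' @param ... passed on to [state_payoffs()] (e.g. Monte Carlo settings).
#' @return updated counts vector.
#' @export
imitation_step <- function(counts, oracle, params, ...) {
  m <- n_strategies(oracle)
  stopifnot(length(counts) == m, sum(counts) == params$N, all(counts >= 0))
  N <- params$N
  # focal individual, reported as its strategy index
  focal <- sample.int(m, 1L, prob = counts)
  if (runif(1) < params$mu) {
    adopt <- sample.int(m, 1L)  # uniform over the full configured set
  } else {
    pi_s <- state_payoffs(oracle, counts, ...)
    avail <- counts - (seq_len(m) == focal)  # role models: the other N - 1
    w <- avail * exp_fitness(pi_s, params$beta, offset = max(pi_s[avail > 0]))
    adopt <- sample.int(m, 1L, prob = w)
  }
  counts[focal] <- counts[focal] - 1L
  counts[adopt] <- counts[adopt] + 1L
  counts
}

#' Long-run imitation dynamics
#'
#' Runs `params$steps` imitation microsteps from `init` (default: each
#' individual assigned a uniformly random strategy) and reports strategy
#' abundances time-averaged after `params$burn_in`, together with a
#' cooperation index: the time average of the population-matched expected
#' cooperation rate `sum_{i,j} x_i (n_j - [i==j])/(N-1) coop[i,j]`.
#'
#' Pairwise oracles run in compiled code; other oracle classes fall back to a
#' (much slower) R loop via [imitation_step()]. Results are exactly
#' reproducible given `params$seed`.
#'
#' @param oracle a payoff oracle.
#' @param params an [evo_params()] object.
#' @param coop cooperation rates: an `m x m` matrix (`coop[i, j]` = rate at
#'   which strategy `i` cooperates against `j`) or a length-`m` vector of
#'   per-strategy rates (recycled across opponents). Default all zero.
#' @param init optional initial counts vector.
#' @return a [stationary_report()] with `method = "simulation"`.
#' @export
run_imitation <- function(oracle, params, coop = NULL, init = NULL) {
  m <- n_strategies(oracle)
  C <- .coop_matrix(coop, m)
  set.seed(params$seed)
  if (is.null(init)) {
    init <- tabulate(sample.int(m, params$N, replace = TRUE), nbins = m)
  }
  stopifnot(sum(init) == params$N)
  if (inherits(oracle, "pairwise_oracle")) {
    res <- run_imitation_pairwise(oracle$A, C, params$N, params$beta,
                                  params$mu, params$steps, params$burn_in,
                                  as.integer(init))
    abund <- res$abundances
    coop_index <- res$coop_index
  } else {
    counts <- as.integer(init)
    abund <- numeric(m)
    coop_index <- 0
    kept <- 0L
    N <- params$N
    for (s in seq_len(params$steps)) {
      counts <- imitation_step(counts, oracle, params)
      if (s > params$burn_in) {
        kept <- kept + 1L
        abund <- abund + counts
        num <- as.numeric(counts %*% C %*% counts) - sum(diag(C) * counts)
        coop_index <- coop_index + num / (N * (N - 1))
      }
    }
    abund <- abund / (kept * N)
    coop_index <- coop_index / kept
  }
  stationary_report(setNames(abund, strategy_labels(oracle)),
                    cooperation_index = coop_index,
                    method = "simulation",
                    params = unclass(params))
}

.coop_matrix <- function(coop, m) {
  if (is.null(coop)) return(matrix(0, m, m))
  if (is.matrix(coop)) {
    stopifnot(nrow(coop) == m, ncol(coop) == m)
    return(coop)
  }
  stopifnot(length(coop) == m)
  matrix(rep(as.numeric(coop), m), nrow = m)
}
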