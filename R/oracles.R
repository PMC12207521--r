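# Payoff oracles decouple the evolutionary dynamics from the game that
# generates payoffs. A pairwise oracle wraps an m x m payoff matrix (two-player
# games); game modules may supply their own oracle classes (e.g. the public
# goods oracle) that know how to compute finite-population payoffs directly.

#' Pairwise payoff oracle
#'
#' Wraps a square payoff matrix `A` where `A[i, j]` is the expected payoff to
#' an `i`-player matched against a `j`-player. Finite-population payoffs
#' exclude self-interaction: an individual of strategy `i` in a population
#' with counts `n` receives `(sum_j A[i,j] n_j - A[i,i]) / (N - 1)`.
#'
#' @param A square numeric payoff matrix (row player's payoff).
#' @param labels character vector of strategy labels; defaults to rownames.
#' @return an object of class `c("pairwise_oracle", "payoff_oracle")`.
#' @export
pairwise_oracle <- function(A, labels = rownames(A)) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("payoff matrix must be square, got ", nrow(A), " x ", ncol(A))
  }
  if (!all(is.finite(A))) stop("payoff matrix must be finite")
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(A)))
  if (length(labels) != nrow(A)) stop("labels length must match matrix dimension")
  structure(list(A = A, labels = as.character(labels)),
            class = c("pairwise_oracle", "payoff_oracle"))
}

#' Strategy labels of a payoff oracle
#' @param oracle a payoff oracle.
#' @return character vector of labels.
#' @export
strategy_labels <- function(oracle) UseMethod("strategy_labels")

#' @export
strategy_labels.payoff_oracle <- function(oracle) oracle$labels

#' Number of strategies known to an oracle
#' @param oracle a payoff oracle.
#' @return integer.
#' @export
n_strategies <- function(oracle) length(strategy_labels(oracle))

#' Expected payoff of one strategy against another
#' @param oracle a payoff oracle.
#' @param i,j strategy indices (payoff to `i` against `j`).
#' @return numeric scalar.
#' @export
pair_payoff <- function(oracle, i, j) UseMethod("pair_payoff")

#' @export
pair_payoff.pairwise_oracle <- function(oracle, i, j) oracle$A[i, j]

#' Per-strategy payoffs in a finite population state
#'
#' Expected payoff of one individual of each strategy when the population has
#' composition `counts` (summing to N), with interactions against a
#' representative sample of the other N - 1 individuals.
#'
#' @param oracle a payoff oracle.
#' @param counts integer vector of strategy counts, `sum(counts) = N`.
#' @param ... passed to methods (e.g. Monte Carlo sample sizes).
#' @return numeric vector, one payoff per strategy (strategies absent from the
#'   population still get the payoff a single such individual would earn).
#' @export
state_payoffs <- function(oracle, counts, ...) UseMethod("state_payoffs")

#' @export
state_payoffs.pairwise_oracle <- function(oracle, counts, ...) {
  stopifnot(length(counts) == n_strategies(oracle))
  N <- sum(counts)
  if (N < 2) stop("need at least 2 individuals")
  as.vector(oracle$A %*% counts - diag(oracle$A)) / (N - 1)
}

#' Finite-population payoff vectors for an invader/resident pair
#'
#' For `j = 1, ..., N - 1` invaders of strategy `invader` in a resident
#' population of strategy `resident`, returns the expected payoffs of one
#' invader and one resident, excluding self-interaction:
#' `pi_inv(j) = ((j-1) a_II + (N-j) a_IR) / (N-1)` and
#' `pi_res(j) = (j a_RI + (N-j-1) a_RR) / (N-1)`.
#'
#' @param oracle a payoff oracle.
#' @param invader,resident strategy indices.
#' @param N population size.
#' @return list with numeric vectors `invader` and `resident`, length `N - 1`.
#' @export
pair_payoff_vectors <- function(oracle, invader, resident, N) {
  UseMethod("pair_payoff_vectors")
}

#' @export
pair_payoff_vectors.pairwise_oracle <- function(oracle, invader, resident, N) {
  if (N < 2) stop("N must be >= 2")
  A <- oracle$A
  j <- seq_len(N - 1)
  list(
    invader  = ((j - 1) * A[invader, invader] + (N - j) * A[invader, resident]) / (N - 1),
    resident = (j * A[resident, invader] + (N - j - 1) * A[resident, resident]) / (N - 1)
  )
}

#' @export
print.payoff_oracle <- function(x, ...) {
  cat("<", class(x)[1], "> over ", n_strategies(x), " strategies: ",
      paste(head(strategy_labels(x), 8), collapse = ", "),
      if (n_strategies(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
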