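# Optional public goods game with peer punishment.
#
# A strategy is a participation class (C cooperate, D defect, L abstain as a
# loner) plus three punishment bits saying whether the strategy punishes
# members of class C, D or L. The full space has 3 * 2^3 = 24 strategies;
# microeconomic restrictions select subsets of 4, 9 or 12.

#' Optional public goods game parameters
#'
#' Contributions `c` are multiplied by `r` and shared; loners sit out for a
#' guaranteed `sigma`. In the punishment stage each set punishment bit costs
#' the punisher `cost_pun` per target and imposes `fine` on each target.
#' The loner payoff should satisfy `0 < sigma < (r - 1) c` (risky collective
#' action beats universal loning beats universal defection); violations warn.
#'
#' @param r multiplication factor of the pool.
#' @param c contribution cost.
#' @param sigma loner payoff.
#' @param fine fine imposed on a target per punisher.
#' @param cost_pun cost paid by a punisher per target.
#' @param n group size (`2 <= n <= N`).
#' @param N population size.
#' @param sharing `"participants"`: the pool `r c n_C` is divided among the
#'   `S` participants; `"others_only"`: each contribution is shared among the
#'   other `S - 1` participants (self-share excluded).
#' @return object of class `pgg_params`.
#' @export
pgg_params <- function(r = 3, c = 1, sigma = 1, fine = 1, cost_pun = 1,
                       n = 5, N = 100,
                       sharing = c("participants", "others_only")) {
  sharing <- match.arg(sharing)
  if (!(sigma > 0 && sigma < (r - 1) * c)) {
    warning("sigma outside (0, (r-1)c): the loner option is not a social ",
            "dilemma escape hatch at these values")
  }
  if (n < 2) stop("group size n must be >= 2")
  if (n > N) stop("group size n must be <= population size N")
  structure(list(r = r, c = c, sigma = sigma, fine = fine,
                 cost_pun = cost_pun, n = as.integer(n), N = as.integer(N),
                 sharing = sharing),
            class = "pgg_params")
}

#' A public-goods strategy
#'
#' @param participation "C", "D" or "L".
#' @param punish_C,punish_D,punish_L logical punishment bits by target class.
#' @return one-row data.frame with a `label` column (e.g. `"C:pD"`, `"L"`).
#' @export
pgg_strategy <- function(participation, punish_C = FALSE, punish_D = FALSE,
                         punish_L = FALSE) {
  if (!participation %in% c("C", "D", "L")) {
    stop("participation must be 'C', 'D' or 'L'")
  }
  bits <- c(C = punish_C, D = punish_D, L = punish_L)
  label <- if (any(bits)) {
    paste0(participation, ":p", paste(names(bits)[bits], collapse = ""))
  } else participation
  data.frame(participation = participation, punish_C = punish_C,
             punish_D = punish_D, punish_L = punish_L, label = label,
             stringsAsFactors = FALSE)
}

#' Restricted public-goods strategy spaces
#'
#' The four nested-or-overlapping spaces arising from different
#' microeconomic assumptions about who may punish whom:
#' * `"four"` -- only cooperators may punish, and only defectors may be
#'   punished: \{C, D, L, C:pD\}.
#' * `"nine"` -- loners can neither punish nor be punished: participation
#'   C/D with all (punish_C, punish_D) combinations, plus the plain loner.
#' * `"twelve"` -- loners cannot be punished but may punish: participation
#'   C/D/L with all (punish_C, punish_D) combinations.
#' * `"full24"` -- everyone can punish and be punished: all 24 strategies.
#'
#' @param restriction one of "four", "nine", "twelve", "full24".
#' @return data.frame of strategies (one row each, see [pgg_strategy()]).
#' @export
pgg_strategy_space <- function(restriction = c("four", "nine", "twelve", "full24")) {
  if (!is.character(restriction) || length(restriction) != 1 ||
      !restriction %in% c("four", "nine", "twelve", "full24")) {
    stop("unknown restriction '", paste(restriction, collapse = ","),
         "'; valid: four, nine, twelve, full24")
  }
  bits2 <- expand.grid(punish_C = c(FALSE, TRUE), punish_D = c(FALSE, TRUE))
  bits3 <- expand.grid(punish_C = c(FALSE, TRUE), punish_D = c(FALSE, TRUE),
                       punish_L = c(FALSE, TRUE))
  rows <- switch(restriction,
    four = list(pgg_strategy("C"), pgg_strategy("D"), pgg_strategy("L"),
                pgg_strategy("C", punish_D = TRUE)),
    nine = c(unlist(lapply(c("C", "D"), function(p) {
               lapply(seq_len(nrow(bits2)), function(i) {
                 pgg_strategy(p, bits2$punish_C[i], bits2$punish_D[i])
               })
             }), recursive = FALSE),
             list(pgg_strategy("L"))),
    twelve = unlist(lapply(c("C", "D", "L"), function(p) {
               lapply(seq_len(nrow(bits2)), function(i) {
                 pgg_strategy(p, bits2$punish_C[i], bits2$punish_D[i])
               })
             }), recursive = FALSE),
    full24 = unlist(lapply(c("C", "D", "L"), function(p) {
               lapply(seq_len(nrow(bits3)), function(i) {
                 pgg_strategy(p, bits3$punish_C[i], bits3$punish_D[i],
                              bits3$punish_L[i])
               })
             }), recursive = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- out$label
  out
}

#' Exact payoffs within one group
#'
#' Stage one: with `S` participants (non-loners) and `n_C` contributors, the
#' game is only played when `S >= 2` -- otherwise every member receives
#' `sigma` and no punishment occurs. When played, participants receive their
#' pool share (per `params$sharing`), contributors additionally pay `c`, and
#' loners receive `sigma`. Stage two: every member whose punishment bit for
#' class X is set pays `cost_pun` per group member of class X (self
#' excluded), and each such target loses `fine` per punisher.
#'
#' @param group data.frame of `n` strategy rows (see [pgg_strategy()]).
#' @param params a [pgg_params()] object.
#' @return numeric payoff vector, one entry per group member.
#' @export
pgg_group_payoffs <- function(group, params) {
  n <- nrow(group)
  if (n != params$n) stop("group size ", n, " != params$n = ", params$n)
  cls <- group$participation
  S <- sum(cls != "L")
  n_C <- sum(cls == "C")
  if (S <= 1) return(rep(params$sigma, n))
  pay <- numeric(n)
  part <- cls != "L"
  contrib <- cls == "C"
  if (params$sharing == "participants") {
    pay[part] <- params$r * params$c * n_C / S
  } else {
    pay[part] <- params$r * params$c * (n_C - contrib[part]) / (S - 1)
  }
  pay[contrib] <- pay[contrib] - params$c
  pay[!part] <- params$sigma
  # punishment stage over all n members, targeting by participation class
  bitmat <- as.matrix(group[, c("punish_C", "punish_D", "punish_L")])
  cnt <- c(C = n_C, D = sum(cls == "D"), L = n - S)
  punishers_of <- c(C = sum(bitmat[, 1]), D = sum(bitmat[, 2]), L = sum(bitmat[, 3]))
  for (i in seq_len(n)) {
    targets <- cnt - (c("C", "D", "L") == cls[i])        # self excluded
    pay[i] <- pay[i] - params$cost_pun * sum(bitmat[i, ] * targets)
    bit_col <- match(cls[i], c("C", "D", "L"))
    pay[i] <- pay[i] - params$fine * (punishers_of[bit_col] - bitmat[i, bit_col])
  }
  unname(pay)
}

#' Per-strategy cooperation indicator
#' @param space data.frame of strategies (or a single [pgg_strategy()] row).
#' @return numeric 0/1 vector: 1 iff participation class is "C".
#' @export
pgg_coop_fraction <- function(space) {
  as.numeric(space$participation == "C")
}

# payoff of a focal individual of strategy `sA` in a group where k of its
# n - 1 co-players play sA and the rest play sB (focal placed first)
.pgg_focal_two_type <- function(sA, sB, k, params) {
  group <- rbind(sA, sA[rep(1, k), , drop = FALSE],
                 sB[rep(1, params$n - 1 - k), , drop = FALSE])
  pgg_group_payoffs(group, params)[1]
}

#' Exact expected payoffs in a two-strategy population
#'
#' With `j` individuals of strategy A and `N - j` of B, a focal individual's
#' `n - 1` co-players are drawn without replacement from the other `N - 1`
#' individuals; the expectation over the hypergeometric group composition of
#' the exact group payoffs is returned. Fully deterministic.
#'
#' @param stratA,stratB one-row strategy data.frames ([pgg_strategy()]).
#' @param j count of A-players, `0 < j < N`.
#' @param params a [pgg_params()] object.
#' @return named numeric vector `c(A = ..., B = ...)`.
#' @export
pgg_expected_payoffs <- function(stratA, stratB, j, params) {
  N <- params$N
  n <- params$n
  if (j <= 0 || j >= N) stop("j must satisfy 0 < j < N")
  k <- 0:(n - 1)
  payA_k <- vapply(k, function(kk) .pgg_focal_two_type(stratA, stratB, kk, params),
                   numeric(1))
  payB_k <- vapply(k, function(kk) {
    # focal B with kk A co-players = payoff of B-focal in group (kk A, n-kk B)
    group <- rbind(stratB, stratA[rep(1, kk), , drop = FALSE],
                   stratB[rep(1, n - 1 - kk), , drop = FALSE])
    pgg_group_payoffs(group, params)[1]
  }, numeric(1))
  wA <- dhyper(k, j - 1, N - j, n - 1)
  wB <- dhyper(k, j, N - j - 1, n - 1)
  c(A = sum(wA * payA_k), B = sum(wB * payB_k))
}

#' Public goods payoff oracle
#'
#' Supplies finite-population payoffs for the evolutionary dynamics. Pairwise
#' invader/resident payoff vectors (used by the small-mutation chain) are
#' exact hypergeometric expectations; full-state payoffs with more than two
#' strategies present are Monte Carlo estimates over sampled groups.
#'
#' @param space strategy data.frame from [pgg_strategy_space()].
#' @param params a [pgg_params()] object.
#' @return an oracle of class `c("pgg_oracle", "payoff_oracle")`.
#' @export
pgg_oracle <- function(space, params) {
  structure(list(space = space, params = params, labels = space$label),
            class = c("pgg_oracle", "payoff_oracle"))
}

#' @export
pair_payoff_vectors.pgg_oracle <- function(oracle, invader, resident, N) {
  params <- oracle$params
  if (N != params$N) stop("N must equal params$N = ", params$N)
  n <- params$n
  sA <- oracle$space[invader, , drop = FALSE]
  sB <- oracle$space[resident, , drop = FALSE]
  k <- 0:(n - 1)
  payA_k <- vapply(k, function(kk) .pgg_focal_two_type(sA, sB, kk, params),
                   numeric(1))
  payB_k <- vapply(k, function(kk) .pgg_focal_two_type(sB, sA, n - 1 - kk, params),
                   numeric(1))
  j <- seq_len(N - 1)
  wA <- outer(j, k, function(jj, kk) dhyper(kk, jj - 1, N - jj, n - 1))
  wB <- outer(j, k, function(jj, kk) dhyper(kk, jj, N - jj - 1, n - 1))
  list(invader = as.vector(wA %*% payA_k),
       resident = as.vector(wB %*% payB_k))
}

#' @export
state_payoffs.pgg_oracle <- function(oracle, counts, ..., n_samples = 2000) {
  params <- oracle$params
  N <- sum(counts)
  if (N != params$N) stop("counts must sum to params$N")
  m <- nrow(oracle$space)
  pay <- numeric(m)
  for (s in seq_len(m)) {
    others <- counts
    others[s] <- others[s] - 1L      # focal excluded; works even if count 0
    if (others[s] < 0) others[s] <- 0L
    pool <- rep(seq_len(m), others)
    tot <- 0
    for (it in seq_len(n_samples)) {
      co <- sample(pool, params$n - 1)
      group <- oracle$space[c(s, co), , drop = FALSE]
      tot <- tot + pgg_group_payoffs(group, params)[1]
    }
    pay[s] <- tot / n_samples
  }
  pay
}
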