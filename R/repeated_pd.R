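# Repeated prisoner's dilemma with reactive (memory-1, opponent-conditioned)
# strategies. Play between two deterministic reactive strategies eventually
# cycles over at most 4 joint states, so discounted payoffs have exact closed
# forms via geometric sums -- no series truncation anywhere.

#' One-shot prisoner's dilemma parameters with discounting
#'
#' The stage game has payoff matrix (R, S; T, P) for (mutual cooperation,
#' sucker, temptation, mutual defection). The game continues to the next
#' round with probability `delta`; repeated-game payoffs are normalised by
#' `1 - delta` so one-shot and repeated payoffs share a scale. The standard
#' ordering `T > R > P > S` and `R > (T + P)/2` is checked with a warning
#' (other orderings are legal games, just not social dilemmas).
#'
#' @param R,S,T,P stage payoffs. Defaults 3, 0, 4, 1.
#' @param delta continuation probability in `[0, 1)`.
#' @return object of class `pd_params`.
#' @export
pd_params <- function(R = 3, S = 0, T = 4, P = 1, delta = 0.9) {
  if (delta < 0 || delta >= 1) {
    stop("delta must lie in [0, 1): payoff normalisation is undefined at delta = 1")
  }
  if (!(T > R && R > P && P > S)) {
    warning("payoffs do not satisfy T > R > P > S; not a prisoner's dilemma")
  } else if (!(R > (T + P) / 2)) {
    warning("R <= (T + P)/2: alternating exploitation beats mutual cooperation")
  }
  structure(list(R = R, S = S, T = T, P = P, delta = delta),
            class = "pd_params")
}

#' Reactive strategy for the repeated prisoner's dilemma
#'
#' A reactive strategy is a triple: first move, reply to an opponent's C,
#' reply to an opponent's D. There are exactly 2^3 = 8 such strategies.
#' An optional complexity cost is subtracted from the strategy's normalised
#' payoff in every interaction (used e.g. to penalise conditional strategies
#' such as Tit-for-Tat relative to unconditional ones).
#'
#' @param first_move,reply_to_C,reply_to_D "C" or "D".
#' @param complexity_cost non-negative per-interaction payoff deduction.
#' @param label optional label; canonical names (AllC, TFT, AllD) are applied
#'   automatically, other strategies default to the move triple (e.g. "CDD").
#' @return object of class `reactive_strategy`.
#' @export
reactive_strategy <- function(first_move, reply_to_C, reply_to_D,
                              complexity_cost = 0, label = NULL) {
  moves <- c(first_move, reply_to_C, reply_to_D)
  if (!all(moves %in% c("C", "D"))) stop("moves must be 'C' or 'D'")
  if (complexity_cost < 0) stop("complexity_cost must be >= 0")
  if (is.null(label)) {
    code <- paste(moves, collapse = "")
    label <- switch(code, CCC = "AllC", CCD = "TFT", DDD = "AllD", code)
  }
  structure(list(first_move = first_move, reply_to_C = reply_to_C,
                 reply_to_D = reply_to_D, complexity_cost = complexity_cost,
                 label = label),
            class = "reactive_strategy")
}

#' @export
print.reactive_strategy <- function(x, ...) {
  cat("<reactive_strategy> ", x$label, ": first ", x$first_move,
      ", vs C -> ", x$reply_to_C, ", vs D -> ", x$reply_to_D,
      if (x$complexity_cost > 0) paste0(" (cost ", x$complexity_cost, ")"),
      "\n", sep = "")
  invisible(x)
}

#' All 8 reactive strategies
#' @param complexity_cost optional named numeric vector of per-strategy costs,
#'   e.g. `c(TFT = 0.05)`.
#' @return list of [reactive_strategy()] objects.
#' @export
all_reactive_strategies <- function(complexity_cost = NULL) {
  grid <- expand.grid(first_move = c("C", "D"), reply_to_C = c("C", "D"),
                      reply_to_D = c("C", "D"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    reactive_strategy(grid$first_move[i], grid$reply_to_C[i], grid$reply_to_D[i])
  })
  names(out) <- vapply(out, function(s) s$label, character(1))
  if (!is.null(complexity_cost)) {
    for (nm in names(complexity_cost)) {
      if (!nm %in% names(out)) stop("unknown strategy label: ", nm)
      out[[nm]]$complexity_cost <- complexity_cost[[nm]]
    }
  }
  out
}

#' Named reactive strategy sets
#'
#' The three canonical strategy-space choices: `"pair"` = \{AllC, AllD\}
#' (one-shot-style dilemma), `"triple"` = \{AllC, TFT, AllD\} (the classic
#' hand-picked set), `"full8"` = all 8 reactive strategies (the unbiased,
#' computationally equivalent set).
#'
#' @param set one of "pair", "triple", "full8".
#' @param complexity_cost optional named costs, as in
#'   [all_reactive_strategies()].
#' @return named list of [reactive_strategy()] objects.
#' @export
pd_strategy_set <- function(set = c("pair", "triple", "full8"),
                            complexity_cost = NULL) {
  if (!is.character(set) || length(set) != 1 ||
      !set %in% c("pair", "triple", "full8")) {
    stop("unknown strategy set '", paste(set, collapse = ","),
         "'; valid sets: pair, triple, full8")
  }
  full <- all_reactive_strategies(complexity_cost)
  switch(set,
         pair = full[c("AllC", "AllD")],
         triple = full[c("AllC", "TFT", "AllD")],
         full8 = full)
}

#' Exact play path of two reactive strategies
#'
#' Deterministic reactive play is a function of the previous joint move, so
#' the infinite play path decomposes into a finite prefix followed by a
#' repeating cycle, together visiting at most 4 distinct joint moves.
#'
#' @param a,b [reactive_strategy()] objects.
#' @return list with character matrices `prefix` and `cycle` (columns `a`,
#'   `b`, one row per round; `prefix` may have zero rows).
#' @export
play_sequence <- function(a, b) {
  reply <- function(s, opp_last) if (opp_last == "C") s$reply_to_C else s$reply_to_D
  moves <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  seen <- character(0)
  ma <- a$first_move
  mb <- b$first_move
  repeat {
    key <- paste0(ma, mb)
    hit <- match(key, seen)
    if (!is.na(hit)) {
      return(list(prefix = moves[seq_len(hit - 1L), , drop = FALSE],
                  cycle = moves[seq(hit, nrow(moves)), , drop = FALSE]))
    }
    seen <- c(seen, key)
    moves <- rbind(moves, c(ma, mb))
    nxt_a <- reply(a, mb)
    nxt_b <- reply(b, ma)
    ma <- nxt_a
    mb <- nxt_b
  }
}

# stage payoff to the row player for a joint move
.stage_payoff <- function(ma, mb, params) {
  ifelse(ma == "C",
         ifelse(mb == "C", params$R, params$S),
         ifelse(mb == "C", params$T, params$P))
}

# normalised discounted sum of a per-round value sequence given the
# prefix/cycle decomposition: (1-d) * [ sum_prefix d^i v_i +
#   d^p / (1 - d^L) * sum_cycle d^k v_k ]
.discounted_value <- function(pref_vals, cyc_vals, delta) {
  p <- length(pref_vals)
  L <- length(cyc_vals)
  pre <- if (p > 0) sum(delta^(seq_len(p) - 1) * pref_vals) else 0
  cyc <- sum(delta^(seq_len(L) - 1) * cyc_vals) * delta^p / (1 - delta^L)
  (1 - delta) * (pre + cyc)
}

#' Exact normalised discounted payoffs of a pair of reactive strategies
#'
#' `(1 - delta) * sum_i delta^i pi_i`, evaluated in closed form from the
#' prefix/cycle decomposition of [play_sequence()] (geometric sums, no
#' truncation). Each strategy's complexity cost is subtracted from its own
#' payoff.
#'
#' @param a,b [reactive_strategy()] objects.
#' @param params a [pd_params()] object.
#' @return named numeric vector `c(a = payoff_a, b = payoff_b)`.
#' @export
discounted_payoff <- function(a, b, params) {
  seqs <- play_sequence(a, b)
  pa <- .discounted_value(.stage_payoff(seqs$prefix[, 1], seqs$prefix[, 2], params),
                          .stage_payoff(seqs$cycle[, 1], seqs$cycle[, 2], params),
                          params$delta) - a$complexity_cost
  pb <- .discounted_value(.stage_payoff(seqs$prefix[, 2], seqs$prefix[, 1], params),
                          .stage_payoff(seqs$cycle[, 2], seqs$cycle[, 1], params),
                          params$delta) - b$complexity_cost
  c(a = pa, b = pb)
}

#' Discounted cooperation rate of a strategy against an opponent
#'
#' The discounted fraction of rounds in which `a` cooperates when playing
#' `b`: `(1 - delta) * sum_i delta^i [a's move at round i == C]`, in `[0, 1]`.
#'
#' @inheritParams discounted_payoff
#' @return numeric scalar.
#' @export
coop_rate <- function(a, b, params) {
  seqs <- play_sequence(a, b)
  .discounted_value(as.numeric(seqs$prefix[, 1] == "C"),
                    as.numeric(seqs$cycle[, 1] == "C"),
                    params$delta)
}

#' Pairwise payoff matrix of a reactive strategy set
#'
#' @param strategies list of [reactive_strategy()] objects.
#' @param params a [pd_params()] object.
#' @return object of class `pd_game`: list with `payoff` (matrix, entry
#'   `[i, j]` = payoff to the row strategy i against j), `coop` (matrix of
#'   pairwise cooperation rates of the row strategy), `self_coop`
#'   (per-strategy self-play cooperation rates) and `params`.
#' @export
pd_payoff_matrix <- function(strategies, params) {
  m <- length(strategies)
  labs <- vapply(strategies, function(s) s$label, character(1))
  A <- matrix(NA_real_, m, m, dimnames = list(labs, labs))
  C <- matrix(NA_real_, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      A[i, j] <- discounted_payoff(strategies[[i]], strategies[[j]], params)[["a"]]
      C[i, j] <- coop_rate(strategies[[i]], strategies[[j]], params)
    }
  }
  structure(list(payoff = A, coop = C, self_coop = diag(C), params = params),
            class = "pd_game")
}

#' @export
print.pd_game <- function(x, ...) {
  cat("<pd_game> ", nrow(x$payoff), " strategies, delta = ",
      x$params$delta, "\n", sep = "")
  print(round(x$payoff, 4))
  invisible(x)
}

#' Payoff oracle for a reactive strategy set
#' @inheritParams pd_payoff_matrix
#' @return a [pairwise_oracle()].
#' @export
pd_oracle <- function(strategies, params) {
  pairwise_oracle(pd_payoff_matrix(strategies, params)$payoff)
}

#' Pure symmetric Nash equilibria of a symmetric matrix game
#'
#' Strategy i is a pure symmetric equilibrium when no deviation against an
#' i-resident pays: `A[i, i] >= A[j, i]` for all j (weak inequality, so ties
#' admit the equilibrium).
#'
#' @param A square payoff matrix (row player's payoff).
#' @return integer vector of equilibrium strategy indices (named when `A`
#'   has rownames).
#' @export
pure_nash <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("payoff matrix must be square")
  idx <- which(vapply(seq_len(nrow(A)),
                      function(i) all(A[i, i] >= A[, i]), logical(1)))
  if (!is.null(rownames(A))) names(idx) <- rownames(A)[idx]
  idx
}
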