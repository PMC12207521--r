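# Indirect reciprocity with binary reputations and private assessment.
#
# Agents play a donation game: a donor decides, from its own opinion of the
# recipient's reputation (Good/Bad), whether to pay `cost` so the recipient
# gains `benefit`. A strategy couples an action rule (what to do facing G or
# B) with a second-order social norm: a map (donor action, recipient
# reputation) -> donor reputation. Every agent keeps a private opinion of
# every other agent; after an interaction, each agent -- including the donor
# judging itself -- applies its own norm to update its opinion of the donor.

#' Donation game and assessment parameters
#'
#' @param benefit benefit to the recipient of a realised cooperation.
#' @param cost cost to the donor (`benefit > cost > 0`).
#' @param N population size.
#' @param rounds_per_gen donation rounds per payoff evaluation (default 100 N).
#' @param assess_error probability an interaction is misperceived: the
#'   observed action is flipped, identically for every observer (a common
#'   perception shock, so error-free monomorphic-norm populations recover
#'   public information exactly).
#' @param exec_error probability an intended cooperation fails (plays D).
#' @return object of class `ir_params`.
#' @export
ir_params <- function(benefit = 5, cost = 1, N = 50L,
                      rounds_per_gen = 100L * N,
                      assess_error = 0.01, exec_error = 0.01) {
  if (!(benefit > cost && cost > 0)) stop("need benefit > cost > 0")
  if (assess_error < 0 || assess_error >= 0.5) stop("assess_error must lie in [0, 0.5)")
  if (exec_error < 0 || exec_error >= 0.5) stop("exec_error must lie in [0, 0.5)")
  if (N < 2) stop("N must be >= 2")
  structure(list(benefit = benefit, cost = cost, N = as.integer(N),
                 rounds_per_gen = as.integer(rounds_per_gen),
                 assess_error = assess_error, exec_error = exec_error),
            class = "ir_params")
}

#' The four action rules
#'
#' ALLC cooperates with everyone, DISC only with the reputable, antiDISC only
#' with the disreputable, ALLD with no one.
#'
#' @return data.frame with columns `label`, `act_on_G`, `act_on_B`.
#' @export
action_rules <- function() {
  data.frame(label = c("ALLC", "DISC", "antiDISC", "ALLD"),
             act_on_G = c("C", "C", "D", "D"),
             act_on_B = c("C", "D", "C", "D"),
             stringsAsFactors = FALSE)
}

#' All 16 second-order social norms
#'
#' A norm assigns the donor a reputation from (donor action, recipient
#' reputation). Each of the 4 input combinations maps to G or B, giving
#' 2^4 = 16 norms, identified by the 4-bit code over the columns
#' (C,G), (C,B), (D,G), (D,B).
#'
#' @return data.frame with columns `label`, `CG`, `CB`, `DG`, `DB`
#'   (values "G"/"B").
#' @export
social_norms <- function() {
  g <- expand.grid(CG = c("B", "G"), CB = c("B", "G"),
                   DG = c("B", "G"), DB = c("B", "G"),
                   stringsAsFactors = FALSE)
  lab <- apply(g, 1, paste, collapse = "")
  data.frame(label = paste0("N", lab), g, stringsAsFactors = FALSE)
}

#' The stern judging norm
#'
#' Cooperating with the good and defecting against the bad earn a good
#' reputation; cooperating with the bad or defecting against the good earn a
#' bad one.
#'
#' @return one-row data.frame in the format of [social_norms()].
#' @export
stern_judging <- function() {
  data.frame(label = "NGBBG", CG = "G", CB = "B", DG = "B", DB = "G",
             stringsAsFactors = FALSE)
}

#' Norm strategy space
#'
#' `"exogenous"`: all agents share one fixed norm (default stern judging) and
#' only the 4 action rules evolve. `"endogenous"`: action rule and norm both
#' evolve, 4 x 16 = 64 strategies.
#'
#' @param space "exogenous" or "endogenous".
#' @param norm the fixed norm for the exogenous space.
#' @return data.frame, one strategy per row: `label`, `rule`, `act_on_G`,
#'   `act_on_B`, `CG`, `CB`, `DG`, `DB`.
#' @export
ir_strategy_space <- function(space = c("exogenous", "endogenous"),
                              norm = stern_judging()) {
  space <- match.arg(space)
  rules <- action_rules()
  norms <- if (space == "exogenous") norm else social_norms()
  out <- merge(rules, norms, by = NULL)
  names(out)[names(out) == "label.x"] <- "rule"
  names(out)[names(out) == "label.y"] <- "norm"
  out$label <- if (space == "exogenous") out$rule else paste0(out$rule, ".", out$norm)
  rownames(out) <- out$label
  out[, c("label", "rule", "norm", "act_on_G", "act_on_B", "CG", "CB", "DG", "DB")]
}

# encode a strategy table for the compiled backend:
# rules: m x 2 integer (act_on_G, act_on_B), 1 = C, 0 = D
# norms: m x 4 integer, column index = 2*action + reputation + 1 over
#        (D,B), (D,G), (C,B), (C,G); 1 = G, 0 = B
.ir_encode <- function(space) {
  rules <- cbind(as.integer(space$act_on_G == "C"),
                 as.integer(space$act_on_B == "C"))
  norms <- cbind(as.integer(space$DB == "G"), as.integer(space$DG == "G"),
                 as.integer(space$CB == "G"), as.integer(space$CG == "G"))
  list(rules = rules, norms = norms)
}

#' Fresh interaction state
#'
#' @param strategies character vector (row labels into `space`) or integer
#'   indices, one per agent.
#' @param space strategy table from [ir_strategy_space()].
#' @return list with `strat` (integer per agent), `space`, `opinions`
#'   (N x N integer matrix, 1 = G, including each agent's self-image on the
#'   diagonal; initialised all good), `payoffs`, `interactions`.
#' @export
ir_state <- function(strategies, space) {
  strat <- if (is.character(strategies)) match(strategies, space$label)
           else as.integer(strategies)
  if (anyNA(strat)) stop("unknown strategy label")
  N <- length(strat)
  list(strat = strat, space = space,
       opinions = matrix(1L, N, N),
       payoffs = numeric(N), interactions = integer(N))
}

#' One donation-game interaction
#'
#' Samples donor and recipient (distinct, uniform), plays the donor's action
#' rule on its own opinion of the recipient (an intended C fails with
#' probability `exec_error`), transfers payoffs if cooperation is realised,
#' and then every agent -- observers and the donor judging itself -- applies
#' its own norm to `(perceived action, its opinion of the recipient)` to
#' update its opinion of the donor. With probability `assess_error` the
#' perceived action is the flip of the realised one, identically for all
#' observers. Uses the current R RNG stream; the number of random draws per
#' round does not depend on any agent's norm, so norm swaps can be coupled
#' on identical streams.
#'
#' @param state an [ir_state()].
#' @param params an [ir_params()] object.
#' @return updated state, with `$last = list(donor, recipient, action)`.
#' @export
interaction_round <- function(state, params) {
  N <- length(state$strat)
  donor <- sample.int(N, 1L)
  recipient <- sample.int(N - 1L, 1L)
  if (recipient >= donor) recipient <- recipient + 1L
  sp <- state$space
  s <- state$strat[donor]
  rep_seen <- state$opinions[donor, recipient]
  action <- if (rep_seen == 1L) sp$act_on_G[s] else sp$act_on_B[s]
  if (action == "C" && runif(1) < params$exec_error) action <- "D"
  if (action == "C") {
    state$payoffs[donor] <- state$payoffs[donor] - params$cost
    state$payoffs[recipient] <- state$payoffs[recipient] + params$benefit
  }
  state$interactions[c(donor, recipient)] <-
    state$interactions[c(donor, recipient)] + 1L
  # every agent k judges the donor with its own norm, from the commonly
  # perceived action
  perceived <- action
  if (runif(1) < params$assess_error) perceived <- if (action == "C") "D" else "C"
  rep_of_recipient <- state$opinions[, recipient]
  col <- if (perceived == "C") c("CB", "CG") else c("DB", "DG")
  assigned <- ifelse(rep_of_recipient == 1L,
                     sp[[col[2]]][state$strat], sp[[col[1]]][state$strat])
  state$opinions[, donor] <- as.integer(assigned == "G")
  state$last <- list(donor = donor, recipient = recipient, action = action)
  state
}

#' Estimate payoffs and cooperation in a fixed population
#'
#' Runs the donation game from all-good opinions, discards an opinion
#' burn-in, then accumulates payoffs over `rounds` interactions. Runs in
#' compiled code; seed the R RNG for reproducibility.
#'
#' @param strategies agent strategies (labels or indices into `space`).
#' @param space strategy table from [ir_strategy_space()].
#' @param params an [ir_params()] object.
#' @param rounds accounted rounds (default `params$rounds_per_gen`).
#' @param burn_in discarded opinion-equilibration rounds (default
#'   `10 * N`).
#' @return list with `payoff_per_round` (per agent), `payoff_per_interaction`
#'   (per agent; 0 for agents never drawn), `coop_rate` (fraction of
#'   accounted rounds with realised cooperation).
#' @export
ir_estimate_payoffs <- function(strategies, space, params,
                                rounds = params$rounds_per_gen,
                                burn_in = 10L * params$N) {
  st <- ir_state(strategies, space)
  enc <- .ir_encode(space)
  res <- ir_simulate_cpp(st$strat - 1L, enc$rules, enc$norms,
                         params$N, params$benefit, params$cost,
                         params$assess_error, params$exec_error,
                         as.integer(rounds), as.integer(burn_in))
  list(payoff_per_round = res$payoffs / rounds,
       payoff_per_interaction = ifelse(res$interactions > 0,
                                       res$payoffs / res$interactions, 0),
       coop_rate = res$coop / rounds)
}

#' Payoff oracle for a norm strategy space
#'
#' Pairwise invader/resident payoff vectors are estimated by simulating the
#' reputation and donation dynamics at every mixed composition (per-type
#' pooled per-interaction payoffs); used by [small_mu_stationary()] /
#' [ir_small_mu()]. Draws from the current R RNG stream.
#'
#' @param space strategy table from [ir_strategy_space()].
#' @param params an [ir_params()] object.
#' @param rounds accounted donation rounds per composition.
#' @param burn_in opinion-equilibration rounds per composition.
#' @return oracle of class `c("ir_oracle", "payoff_oracle")`.
#' @export
ir_oracle <- function(space, params, rounds = 1000L, burn_in = 300L) {
  structure(list(space = space, params = params, enc = .ir_encode(space),
                 rounds = as.integer(rounds), burn_in = as.integer(burn_in),
                 labels = space$label),
            class = c("ir_oracle", "payoff_oracle"))
}

#' @export
pair_payoff_vectors.ir_oracle <- function(oracle, invader, resident, N) {
  p <- oracle$params
  if (N != p$N) stop("N must equal params$N = ", p$N)
  idx <- c(invader, resident)
  ir_pair_vectors_cpp(oracle$enc$rules[idx, , drop = FALSE],
                      oracle$enc$norms[idx, , drop = FALSE],
                      N, p$benefit, p$cost, p$assess_error, p$exec_error,
                      oracle$rounds, oracle$burn_in)
}

#' Small-mutation-limit dynamics over a norm strategy space
#'
#' Builds the embedded Markov chain over monomorphic states with fixation
#' probabilities computed from simulated invader/resident payoff vectors,
#' and weights each strategy's long-run abundance by its monomorphic realised
#' cooperation rate (also simulated). Stochastic only through the payoff
#' estimates; fully reproducible given `seed`.
#'
#' @param space strategy table from [ir_strategy_space()] (or
#'   "exogenous"/"endogenous").
#' @param params an [ir_params()] object.
#' @param beta selection intensity.
#' @param seed RNG seed.
#' @param rounds,burn_in simulation effort per pairwise composition (see
#'   [ir_oracle()]).
#' @param coop_rounds accounted rounds for each monomorphic cooperation rate.
#' @return a [stationary_report()] with `method = "small_mu"`.
#' @export
ir_small_mu <- function(space, params, beta = 1, seed = 1L,
                        rounds = 1000L, burn_in = 300L,
                        coop_rounds = 5000L) {
  if (is.character(space)) space <- ir_strategy_space(space)
  set.seed(seed)
  m <- nrow(space)
  coop <- vapply(seq_len(m), function(s) {
    ir_estimate_payoffs(rep(s, params$N), space, params,
                        rounds = coop_rounds)$coop_rate
  }, numeric(1))
  rep_obj <- small_mu_stationary(ir_oracle(space, params, rounds, burn_in),
                                 params$N, beta, coop = coop,
                                 params = c(unclass(params),
                                            list(seed = seed, rounds = rounds,
                                                 coop_rounds = coop_rounds)))
  rep_obj
}

#' Evolutionary dynamics over a norm strategy space
#'
#' Agent-based imitation dynamics: reputations evolve continuously while,
#' after every window of `rounds_per_step` donation rounds, one imitation
#' microstep runs using the window's per-interaction average payoffs and the
#' exponential fitness mapping (exploration rate `evo$mu`, uniform over the
#' space). An agent whose strategy changes has its outgoing opinions reset to
#' good; others' opinions of it persist. Strategy abundances are time
#' averages after `evo$burn_in` steps; the cooperation index is the realised
#' cooperation fraction over the accounted rounds.
#'
#' @param space strategy table from [ir_strategy_space()] (or the string
#'   "exogenous"/"endogenous").
#' @param params an [ir_params()] object.
#' @param evo an [evo_params()] object (`evo$N` must equal `params$N`).
#' @param rounds_per_step donation rounds per imitation step (default 10 N).
#' @return a [stationary_report()] with `method = "simulation"`.
#' @export
ir_evolve <- function(space, params, evo, rounds_per_step = 10L * params$N) {
  if (is.character(space)) space <- ir_strategy_space(space)
  if (evo$N != params$N) stop("evo$N must equal params$N")
  enc <- .ir_encode(space)
  m <- nrow(space)
  set.seed(evo$seed)
  init <- sample.int(m, params$N, replace = TRUE) - 1L
  res <- ir_evolve_cpp(enc$rules, enc$norms, params$N,
                       params$benefit, params$cost,
                       params$assess_error, params$exec_error,
                       evo$beta, evo$mu, evo$steps, evo$burn_in,
                       as.integer(rounds_per_step), init)
  stationary_report(setNames(res$abundances, space$label),
                    cooperation_index = res$coop_index,
                    method = "simulation",
                    params = c(unclass(params), unclass(evo),
                               list(rounds_per_step = rounds_per_step)))
}
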