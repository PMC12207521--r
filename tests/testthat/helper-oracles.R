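# Independent oracles used to cross-check the closed-form implementations.

# Truncated-series repeated-game payoff: simulate rounds until the geometric
# tail bound drops below `tol`, then sum (1 - delta) * delta^i * pi_i.
series_payoff <- function(a, b, params, tol = 1e-12) {
  d <- params$delta
  maxpay <- max(abs(c(params$R, params$S, params$T, params$P)))
  reply <- function(s, opp) if (opp == "C") s$reply_to_C else s$reply_to_D
  stage <- function(ma, mb) {
    if (ma == "C") { if (mb == "C") params$R else params$S }
    else           { if (mb == "C") params$T else params$P }
  }
  total <- 0
  ma <- a$first_move; mb <- b$first_move
  w <- 1  # d^i, tracked multiplicatively
  i <- 0
  while (w * maxpay >= tol || i == 0) {
    total <- total + w * stage(ma, mb)
    nxt_a <- reply(a, mb); nxt_b <- reply(b, ma)
    ma <- nxt_a; mb <- nxt_b
    w <- w * d
    i <- i + 1
    if (i > 1e6) stop("series oracle failed to converge")
  }
  (1 - d) * total - a$complexity_cost
}

# Absorbing tridiagonal birth-death chain solve for the fixation probability,
# using jump probabilities whose ratio is exp(-beta * (piA - piB)).
# Conditioned on a move, the chain jumps up with q_j = T+/(T+ + T-), so the
# absorption system is h_j = q_j h_{j+1} + (1 - q_j) h_{j-1}, h_0 = 0,
# h_N = 1. The tridiagonal system is eliminated in ratio form,
# s_j = h_{j-1}/h_j with t_j = 1 - s_j tracked by the subtraction-free
# recurrence t' = (1-q) t / (t + q (1 - t)): every operation is a positive
# sum or product, so the solve stays accurate even when selection makes the
# naive matrix solve singular to machine precision.
fixation_chain_solve <- function(pi_invader, pi_resident, beta) {
  N <- length(pi_invader) + 1
  z <- beta * (pi_invader - pi_resident)
  q <- 1 / (1 + exp(-z))
  qc <- 1 / (1 + exp(z))  # 1 - q without cancellation
  if (N == 2) return(q[1])
  s <- numeric(N - 1)     # s[j] = h_{j-1}/h_j for j = 2..N-1
  s[2] <- q[1]
  tj <- qc[1]
  if (N > 3) for (j in 2:(N - 2)) {
    denom <- tj + q[j] * (1 - tj)
    s[j + 1] <- q[j] / denom
    tj <- qc[j] * tj / denom
  }
  h_top <- q[N - 1] / (tj + q[N - 1] * (1 - tj))
  exp(log(h_top) + sum(log(s[2:(N - 1)])))
}

# Closed-form replicator solution for a 2-strategy game with constant payoff
# difference k = pi_1 - pi_2 (independent of x): logistic growth/decay of x_1.
replicator_logistic <- function(x0, k, t) {
  x0 * exp(k * t) / (1 - x0 + x0 * exp(k * t))
}

fig1_pd <- function(delta = 0.9) pd_params(R = 3, S = 0, T = 4, P = 1, delta = delta)
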