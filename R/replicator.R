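# Deterministic replicator dynamics on the strategy simplex.

#' Right-hand side of the replicator equation
#'
#' For frequencies `x` and pairwise payoff matrix `A`, strategy i changes at
#' rate `x_i * ((A x)_i - x' A x)`: growth proportional to the excess of a
#' strategy's payoff over the population average. The components always sum
#' to zero, so the simplex is invariant.
#'
#' @param x numeric frequency vector (non-negative, sums to 1 within 1e-9).
#' @param A square payoff matrix with `nrow(A) == length(x)`.
#' @return numeric vector of time derivatives.
#' @export
replicator_rhs <- function(x, A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("payoff matrix must be square")
  if (length(x) != nrow(A)) {
    stop("dimension mismatch: length(x) = ", length(x),
         " but A is ", nrow(A), " x ", ncol(A))
  }
  if (any(x < -1e-9) || abs(sum(x) - 1) > 1e-9) {
    stop("x must lie on the simplex (entries >= 0, sum = 1)")
  }
  f <- as.vector(A %*% x)
  x * (f - sum(x * f))
}

#' Integrate the replicator dynamics
#'
#' Fixed-step classical 4th-order Runge-Kutta integration, with the state
#' renormalised onto the simplex after every step (negative round-off clipped
#' to zero). Fixed stepping is used for exact reproducibility.
#'
#' @param x0 initial frequency vector on the simplex.
#' @param A square payoff matrix.
#' @param t_end final time (> 0).
#' @param dt step size (default 0.01).
#' @return object of class `replicator_trajectory`: list with `times` (numeric
#'   vector) and `states` (matrix, one row per time point, columns named by
#'   `rownames(A)` when present).
#' @export
integrate_replicator <- function(x0, A, t_end, dt = 0.01) {
  if (dt <= 0) stop("dt must be positive")
  if (t_end <= 0) stop("t_end must be positive")
  A <- as.matrix(A)
  n_steps <- as.integer(ceiling(t_end / dt))
  m <- length(x0)
  states <- matrix(NA_real_, nrow = n_steps + 1L, ncol = m)
  colnames(states) <- rownames(A)
  x <- x0 / sum(x0)
  states[1L, ] <- x
  for (s in seq_len(n_steps)) {
    k1 <- replicator_rhs(x, A)
    k2 <- .rhs_raw(x + dt / 2 * k1, A)
    k3 <- .rhs_raw(x + dt / 2 * k2, A)
    k4 <- .rhs_raw(x + dt * k3, A)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x))) {
      stop("replicator integration produced a non-finite state at step ", s,
           " (t = ", s * dt, "); state: ", paste(signif(x, 4), collapse = ", "))
    }
    x <- pmax(x, 0)
    x <- x / sum(x)
    states[s + 1L, ] <- x
  }
  structure(list(times = seq(0, by = dt, length.out = n_steps + 1L),
                 states = states),
            class = "replicator_trajectory")
}

# internal RK stage evaluation: skips the simplex check since intermediate
# stages may drift off the simplex by O(dt)
.rhs_raw <- function(x, A) {
  f <- as.vector(A %*% x)
  x * (f - sum(x * f))
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  ns <- nrow(x$states)
  cat("<replicator_trajectory> ", ns, " states, t in [0, ",
      x$times[ns], "]\n", sep = "")
  cat("endpoint:", paste(signif(x$states[ns, ], 4), collapse = " "), "\n")
  invisible(x)
}
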