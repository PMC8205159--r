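# Adaptive world-model: transition pseudo-counts with a Dirichlet-style
# prior, Bayes-Factor surprise of observed transitions, and the variational
# SMiLe update that interpolates between incrementing and resetting the
# pseudo-counts according to surprise. Model-based Q-values are kept
# consistent with the world-model by prioritized sweeping.

#' Transition pseudo-count table
#'
#' @param n_states,n_actions Table dimensions (goal state has no actions but
#'   is a valid successor).
#' @return A numeric array `[state, action, successor]` of zeros.
#' @export
pseudo_count_table <- function(n_states = 11L, n_actions = 4L) {
  array(0, dim = c(n_states - 1L, n_actions, n_states))
}

#' Model transition probability
#'
#' `(C~(s,a->s') + eps) / (C~(s,a) + n_states * eps)` where `C~(s,a)` is the
#' successor sum of the pseudo-counts. With all-zero pseudo-counts every
#' successor has probability `1/n_states`.
#'
#' @param pc Pseudo-count array from [pseudo_count_table()].
#' @param epsilon Positive prior weight.
#' @param s,a,s_next State, action, successor labels.
#' @export
transition_probability <- function(pc, epsilon, s, a, s_next) {
  stopifnot(epsilon > 0)
  n_states <- dim(pc)[3]
  (pc[s, a, s_next] + epsilon) / (sum(pc[s, a, ]) + n_states * epsilon)
}

#' Bayes-Factor surprise of a transition
#'
#' The ratio of the reset (uniform, `1/n_states`) transition probability to
#' the model's transition probability: 1 when the model predicts uniformly,
#' large when the model confidently predicted something else. Equal to
#' `(1/n_states) / (1 - SPE)` where `SPE = 1 - p` is the state prediction
#' error.
#'
#' @param p_transition Model probability of the observed transition, in
#'   (0, 1].
#' @param n_states Number of states (default 11).
#' @export
bayes_factor_surprise <- function(p_transition, n_states = 11L) {
  if (any(p_transition <= 0)) stop("transition probability must be positive")
  (1 / n_states) / p_transition
}

#' Surprise-modulated adaptation factor
#'
#' `gamma = m * S_BF / (1 + m * S_BF)`, in \[0, 1\]: 0 for unsurprising
#' transitions (or m = 0), approaching 1 as surprise grows.
#'
#' @param s_bf Bayes-Factor surprise (non-negative).
#' @param m Volatility parameter (non-negative).
#' @export
adaptation_factor <- function(s_bf, m) {
  stopifnot(all(s_bf >= 0), all(m >= 0))
  m * s_bf / (1 + m * s_bf)
}

#' Variational SMiLe pseudo-count update
#'
#' Scales the pseudo-counts of the active `(s, a)` row by `1 - gamma` and
#' adds 1 to the observed successor. `gamma = 0` is a plain count increment;
#' `gamma = 1` resets the row so the observed transition counts as the first
#' one. All other rows are untouched.
#'
#' @param pc Pseudo-count array.
#' @param gamma Adaptation factor in \[0, 1\].
#' @param s,a,s_next The observed transition.
#' @export
smile_update <- function(pc, gamma, s, a, s_next) {
  stopifnot(gamma >= 0, gamma <= 1)
  pc[s, a, ] <- (1 - gamma) * pc[s, a, ]
  pc[s, a, s_next] <- pc[s, a, s_next] + 1
  pc
}

#' Solve model-based Q-values against the current world-model
#'
#' Computes Q-values satisfying the Bellman equations under the model's
#' transition probabilities, either exactly by value iteration or by
#' prioritized sweeping with a bounded backup budget (the anytime scheme
#' used inside the agents). The goal state is terminal with zero
#' continuation value.
#'
#' @param pc Pseudo-count array.
#' @param epsilon Prior weight of the transition model.
#' @param reward Either a numeric vector of per-successor rewards (length
#'   `n_states`) or a function `(s, a, s_next) -> reward`.
#' @param discount Discount factor in \[0, 1).
#' @param method `"value_iteration"` (exact, default) or
#'   `"prioritized_sweeping"`.
#' @param t_ps Backup budget for prioritized sweeping (total state
#'   re-evaluations).
#' @param tol Convergence tolerance on the value function.
#' @param q_init Initial Q-value (optimistic initialization uses a positive
#'   value).
#' @return Matrix `[state, action]` of Q-values over non-goal states.
#' @export
solve_mb_values <- function(pc, epsilon, reward, discount,
                            method = c("value_iteration", "prioritized_sweeping"),
                            t_ps = 1000L, tol = 1e-10, q_init = 0) {
  stopifnot(discount >= 0, discount < 1)
  method <- match.arg(method)
  n_s <- dim(pc)[3]
  n_sa <- dim(pc)[1]
  n_a <- dim(pc)[2]
  rfun <- if (is.function(reward)) reward else function(s, a, s_next) reward[s_next]
  # Dense probability and reward tables.
  P <- array(0, dim = c(n_sa, n_a, n_s))
  R <- array(0, dim = c(n_sa, n_a, n_s))
  for (s in seq_len(n_sa)) for (a in seq_len(n_a)) {
    P[s, a, ] <- (pc[s, a, ] + epsilon) / (sum(pc[s, a, ]) + n_s * epsilon)
    for (sn in seq_len(n_s)) R[s, a, sn] <- rfun(s, a, sn)
  }
  q <- matrix(q_init, n_sa, n_a)
  backup_state <- function(q, s) {
    v <- c(apply(q, 1, max), 0)  # V(goal) = 0
    for (a in seq_len(n_a))
      q[s, a] <- sum(P[s, a, ] * (R[s, a, ] + discount * v * c(rep(1, n_sa), 0)))
    q
  }
  if (method == "value_iteration") {
    for (iter in seq_len(10000L)) {
      v_old <- apply(q, 1, max)
      for (s in seq_len(n_sa)) q <- backup_state(q, s)
      if (max(abs(apply(q, 1, max) - v_old)) < tol) break
    }
    if (iter == 10000L) warning("value iteration did not converge; residual = ",
                                max(abs(apply(q, 1, max) - v_old)))
  } else {
    pri <- rep(Inf, n_sa)  # every state starts on the queue
    for (k in seq_len(t_ps)) {
      s <- which.max(pri)
      if (pri[s] <= tol) break
      v_before <- max(q[s, ])
      q <- backup_state(q, s)
      pri[s] <- 0
      dv <- abs(max(q[s, ]) - v_before)
      if (dv > tol) {
        # the smoothed model links every state pair
        for (u in seq_len(n_sa)) {
          pri[u] <- max(pri[u], dv * max(P[u, , s]))
        }
      }
    }
    if (max(pri) > 1e-3 && is.finite(max(pri)))
      warning("prioritized sweeping stopped at budget with residual priority ",
              signif(max(pri), 3))
  }
  q
}
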