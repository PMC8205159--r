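# Model-free TD learning with two reward channels (external reward and
# novelty), replacing eligibility traces, and a learning rate modulated by
# the world-model's surprise.

#' TD prediction error for one channel
#'
#' `PE = signal + discount * max_a' Q(s_next, a') - Q(s, a)`, with the value
#' of the goal state defined as 0 (terminal). Used identically for the
#' reward channel (RPE, external reward, discount `lambda_R`) and the
#' novelty channel (NPE, novelty signal, discount `lambda_N`).
#'
#' @param signal The channel's reward-like signal for this transition.
#' @param q Q-table matrix `[state, action]` over non-goal states.
#' @param s,a,s_next The transition (labels; `s_next` may be the goal).
#' @param discount Discount factor in \[0, 1\].
#' @param goal Goal state label (terminal).
#' @export
prediction_error <- function(signal, q, s, a, s_next, discount, goal = 11L) {
  v_next <- if (s_next == goal) 0 else max(q[s_next, ])
  signal + discount * v_next - q[s, a]
}

#' Update replacing eligibility traces
#'
#' The just-visited pair is set to 1; all other entries decay by
#' `lambda * mu`. Traces are re-initialized at zero at the start of every
#' episode (see [reset_traces()]).
#'
#' @param traces Trace matrix `[state, action]`.
#' @param s,a The visited pair.
#' @param lambda_ Channel discount factor.
#' @param mu Channel trace-decay factor in \[0, 1\].
#' @export
update_traces <- function(traces, s, a, lambda_, mu) {
  traces <- traces * (lambda_ * mu)
  traces[s, a] <- 1
  traces
}

#' @rdname update_traces
#' @param n_states,n_actions Trace table dimensions (non-goal states).
#' @export
reset_traces <- function(n_states = 10L, n_actions = 4L) {
  matrix(0, n_states, n_actions)
}

#' Surprise-modulated learning rate
#'
#' `rho = rho_b + gamma * delta_rho`: the baseline rate for expected
#' transitions, increased by up to `delta_rho` at saturating surprise.
#'
#' @param gamma Adaptation factor in \[0, 1\].
#' @param rho_b Baseline learning rate.
#' @param delta_rho Surprise increment.
#' @export
modulated_learning_rate <- function(gamma, rho_b, delta_rho) {
  stopifnot(all(gamma >= 0), all(gamma <= 1), rho_b >= 0, delta_rho >= 0)
  rho_b + gamma * delta_rho
}

#' TD update of a Q-table through eligibility traces
#'
#' Every pair moves by `rho * e(s, a) * PE`; pairs with zero trace are
#' unchanged.
#'
#' @param q Q-table matrix.
#' @param traces Eligibility-trace matrix (same shape).
#' @param pe Scalar prediction error.
#' @param rho Learning rate (non-negative).
#' @export
td_update <- function(q, traces, pe, rho) {
  stopifnot(rho >= 0)
  q + rho * traces * pe
}
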