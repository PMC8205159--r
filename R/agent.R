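# Agent assembly: wiring the novelty system, the adaptive world-model and
# the surprise-modulated TD learner behind a single step/act interface.
#
# This file is the readable reference implementation in plain R, composing
# the exported primitive operations in the documented fixed order:
#   (1) read the novelty reward from pre-update counts;
#   (2) compute Bayes-Factor surprise from the pre-update world-model;
#   (3) SMiLe-update the pseudo-counts;
#   (4) record the observation in the novelty counts;
#   (5) model-free updates (traces, prediction errors, TD step);
#   (6) prioritized-sweeping update of the model-based Q-values;
#   (7) action choice happens at the new state on the next call.
# The compiled core used by simulation and likelihood fitting implements
# the identical schedule; a parity test holds the two together.

PS_TOL <- 1e-9
PRED_CUTOFF <- 1e-2

#' Build an agent
#'
#' @param model Model name from [model_roster()].
#' @param params Parameter set from [surnor_params()].
#' @return An object of class `surnor_agent` holding all learner state:
#'   state counts, transition pseudo-counts, the four Q-tables, the two
#'   eligibility-trace tables and the prioritized-sweeping priorities.
#' @export
build_agent <- function(model = "SurNoR", params = surnor_params()) {
  spec <- model_spec(model)
  flags <- spec_flags(spec)
  p <- as.numeric(params); names(p) <- names(unclass(params))
  uses_mb <- spec$policy %in% c("MB", "Hyb")
  uses_mf <- spec$policy %in% c("MF", "Hyb")
  nov_channel <- spec$exploration %in% c("novelty", "uncertainty", "binary_novelty")
  oi <- spec$exploration == "optimistic_init"
  structure(list(
    spec = spec, flags = flags, params = p,
    uses_mb = uses_mb, uses_mf = uses_mf, nov_channel = nov_channel,
    uses_wm = uses_mb || spec$surprise_mod || spec$exploration == "uncertainty",
    counts = state_counts(),
    pc = pseudo_count_table(),
    q_mb_r = matrix(if (oi) p[["q_oi"]] else 0, 10, 4),
    q_mb_n = matrix(0, 10, 4),
    q_mf_r = matrix(if (oi) p[["q_oi"]] else 0, 10, 4),
    q_mf_n = matrix(if (nov_channel) p[["q_n0"]] else 0, 10, 4),
    e_r = reset_traces(), e_n = reset_traces(),
    # classic prioritized sweeping: every state starts on the queue
    pri_r = rep(Inf, 10), pri_n = rep(Inf, 10)),
    class = "surnor_agent")
}

#' @export
print.surnor_agent <- function(x, ...) {
  cat("Agent:", x$spec$name, sprintf("(policy %s, exploration %s, surprise modulation %s)\n",
      x$spec$policy, x$spec$exploration, if (x$spec$surprise_mod) "on" else "off"))
  cat("Free parameters:", length(free_parameters(x$spec)), "\n")
  cat("Observations so far:", x$counts$t, "\n")
  invisible(x)
}

#' Start a new episode
#'
#' Resets both eligibility traces to zero and records the observation of
#' the episode's start state.
#'
#' @param agent A `surnor_agent`.
#' @param start_state Displayed start state of the episode.
#' @export
agent_begin_episode <- function(agent, start_state) {
  agent$e_r <- reset_traces()
  agent$e_n <- reset_traces()
  agent$counts <- record_observation(agent$counts, start_state)
  agent
}

# Per-step novelty weight: novelty values enter the policy only in the
# first episode of each block.
novelty_weight <- function(agent, block, episode) {
  if (!agent$nov_channel || episode != 1L) return(0)
  if (block == 1L) agent$params[["beta_n1"]] else agent$params[["beta_n2"]]
}

#' Action probabilities of the hybrid softmax policy
#'
#' Softmax over a weighted combination of the model-based and model-free
#' Q-values for reward and (in the first episode of each block) novelty.
#'
#' @param agent A `surnor_agent`.
#' @param s Displayed state.
#' @param block,episode Episode context (novelty weights apply only in
#'   episode 1 of each block; block selects the softmax temperature).
#' @return Numeric vector of 4 probabilities.
#' @export
action_probabilities <- function(agent, s, block, episode) {
  if (agent$spec$policy == "RC") return(rep(0.25, 4))
  u <- combined_values(agent, s, block, episode)
  beta <- if (block == 1L) agent$params[["beta_1"]] else agent$params[["beta_2"]]
  z <- beta * u
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

combined_values <- function(agent, s, block, episode) {
  p <- agent$params
  bn <- novelty_weight(agent, block, episode)
  switch(agent$spec$policy,
    MB = agent$q_mb_r[s, ] + bn * agent$q_mb_n[s, ],
    MF = agent$q_mf_r[s, ] + bn * agent$q_mf_n[s, ],
    Hyb = {
      om <- p[["omega_0"]]
      om1b <- if (block == 1L) p[["omega_11"]] else p[["omega_12"]]
      p[["omega_scale"]] * (om * agent$q_mb_r[s, ] + (1 - om) * agent$q_mf_r[s, ] +
        bn * (om1b * agent$q_mb_n[s, ] + (1 - om1b) * agent$q_mf_n[s, ]))
    },
    stop("policy has no combined values"))
}

# Branch values used by the effective-weight/dominance analysis.
branch_values <- function(agent, s, block, episode) {
  bn <- novelty_weight(agent, block, episode)
  list(mf = agent$q_mf_r[s, ] + bn * agent$q_mf_n[s, ],
       mb = agent$q_mb_r[s, ] + bn * agent$q_mb_n[s, ])
}

# Intrinsic (novelty-channel) reward signal for an observed transition,
# computed from pre-update counts/model.
channel_signal <- function(agent, s_next, s_bf) {
  switch(agent$spec$exploration,
    novelty = novelty(agent$counts, s_next),
    uncertainty = log(s_bf),
    binary_novelty = {
      if (agent$spec$binary_novelty == "threshold") {
        -as.numeric(agent$counts$counts[s_next] > agent$params[["bn_theta"]])
      } else {
        cnt <- agent$counts$counts
        n <- as.integer(round(agent$params[["bn_n"]]))
        ord <- order(-cnt, seq_along(cnt))  # ties: lower state label first
        flagged <- head(ord[cnt[ord] > 0], n)
        -as.numeric(s_next %in% flagged)
      }
    },
    0)
}

#' Advance the agent by one observed transition
#'
#' Executes the fixed update order and returns the updated agent together
#' with the per-trial model variables (Surprise, Novelty, NPE, RPE, Reward)
#' that downstream regression analyses consume.
#'
#' @param agent A `surnor_agent` (an episode must have been started).
#' @param s,a,s_next,reward The observed transition (displayed labels).
#' @param block,episode Episode context.
#' @return List with `agent` and `vars` (named numeric vector).
#' @export
agent_step <- function(agent, s, a, s_next, reward, block, episode) {
  stopifnot(s >= 1, s <= 10, a >= 1, a <= 4, s_next >= 1, s_next <= 11)
  p <- agent$params
  # (1) novelty reward from pre-update counts
  nov <- novelty(agent$counts, s_next)
  # (2) surprise from the pre-update world-model
  s_bf <- if (agent$uses_wm) {
    bayes_factor_surprise(transition_probability(agent$pc, p[["epsilon"]], s, a, s_next))
  } else 0
  gamma <- if (agent$spec$surprise_mod) adaptation_factor(s_bf, p[["m"]]) else 0
  n_sig <- channel_signal(agent, s_next, s_bf)
  # (3) SMiLe update of the pseudo-counts
  if (agent$uses_wm) {
    g_wm <- if (agent$spec$surprise_mod) gamma else p[["gamma_leak"]]
    agent$pc <- smile_update(agent$pc, g_wm, s, a, s_next)
  }
  # (4) record the observation
  if (s_next != GOAL_STATE || agent$flags$count_goal == 1L)
    agent$counts <- record_observation(agent$counts, s_next)
  # (5) model-free updates
  rpe <- 0; npe <- 0
  if (agent$uses_mf) {
    agent$e_r <- update_traces(agent$e_r, s, a, p[["lambda_r"]], p[["mu_r"]])
    rho <- modulated_learning_rate(gamma, p[["rho_b"]],
                                   if (agent$spec$surprise_mod) p[["delta_rho"]] else 0)
    rpe <- prediction_error(reward, agent$q_mf_r, s, a, s_next, p[["lambda_r"]])
    agent$q_mf_r <- td_update(agent$q_mf_r, agent$e_r, rpe, rho)
    if (agent$nov_channel) {
      agent$e_n <- update_traces(agent$e_n, s, a, p[["lambda_n"]], p[["mu_n"]])
      npe <- prediction_error(n_sig, agent$q_mf_n, s, a, s_next, p[["lambda_n"]])
      agent$q_mf_n <- td_update(agent$q_mf_n, agent$e_n, npe, rho)
    }
  }
  # (6) model-based value sweeps
  if (agent$uses_mb) {
    agent <- ps_sweep(agent, "r", s, s_next)
    if (agent$nov_channel) agent <- ps_sweep(agent, "n", s, s_next)
  }
  list(agent = agent,
       vars = c(surprise = s_bf, novelty = nov, npe = npe, rpe = rpe,
                reward = as.numeric(reward)))
}

# One prioritized-sweeping pass for a channel ("r" = external reward,
# "n" = novelty/intrinsic). Priorities persist across steps; the active
# state (and for the novelty channel, the just-observed state and its
# predecessors, whose reward changed) are re-queued with top priority.
ps_sweep <- function(agent, channel, s, s_next) {
  p <- agent$params
  eps <- p[["epsilon"]]
  t_ps <- as.integer(round(p[["t_ps"]]))
  if (channel == "r") {
    q <- agent$q_mb_r; pri <- agent$pri_r; disc <- p[["lambda_r"]]
  } else {
    q <- agent$q_mb_n; pri <- agent$pri_n; disc <- p[["lambda_n"]]
  }
  rew <- mb_reward_table(agent, channel)
  pri[s] <- Inf
  if (channel == "n" && s_next != GOAL_STATE) {
    pri[s_next] <- Inf
    for (u in 1:10) if (any(agent$pc[u, , s_next] > PRED_CUTOFF)) pri[u] <- Inf
  }
  v <- apply(q, 1, max)
  for (k in seq_len(t_ps)) {
    st <- which.max(pri)
    if (pri[st] <= PS_TOL) break
    v_before <- max(q[st, ])
    for (a in 1:4) {
      row <- agent$pc[st, a, ]
      pr <- (row + eps) / (sum(row) + 11 * eps)
      q[st, a] <- sum(pr * (rew[st, a, ] + disc * c(v, 0)))
    }
    pri[st] <- 0
    v[st] <- max(q[st, ])
    dv <- abs(v[st] - v_before)
    if (dv > PS_TOL) {
      # under the smoothed model every state is a potential predecessor of
      # every other; priorities weight the value change by the strongest
      # transition probability into the changed state
      for (u in 1:10) {
        p_in <- 0
        for (a in 1:4) {
          cand <- (agent$pc[u, a, st] + eps) / (sum(agent$pc[u, a, ]) + 11 * eps)
          if (cand > p_in) p_in <- cand
        }
        pri[u] <- max(pri[u], dv * p_in)
      }
    }
  }
  if (channel == "r") { agent$q_mb_r <- q; agent$pri_r <- pri }
  else { agent$q_mb_n <- q; agent$pri_n <- pri }
  agent
}

# Per-(s, a, s') reward table for the model-based planner of a channel.
mb_reward_table <- function(agent, channel) {
  rew <- array(0, dim = c(10, 4, 11))
  if (channel == "r") {
    rew[, , GOAL_STATE] <- 1
    return(rew)
  }
  p <- agent$params
  eps <- p[["epsilon"]]
  switch(agent$spec$exploration,
    novelty = {
      nv <- vapply(1:11, function(sn) novelty(agent$counts, sn), 0)
      for (sn in 1:11) rew[, , sn] <- nv[sn]
    },
    uncertainty = {
      for (st in 1:10) for (a in 1:4) {
        row <- agent$pc[st, a, ]
        pr <- (row + eps) / (sum(row) + 11 * eps)
        rew[st, a, ] <- log((1 / 11) / pr)
      }
    },
    binary_novelty = {
      for (sn in 1:11) {
        flag <- if (agent$spec$binary_novelty == "threshold") {
          agent$counts$counts[sn] > p[["bn_theta"]]
        } else {
          cnt <- agent$counts$counts
          n <- as.integer(round(p[["bn_n"]]))
          ord <- order(-cnt, seq_along(cnt))
          sn %in% head(ord[cnt[ord] > 0], n)
        }
        rew[, , sn] <- -as.numeric(flag)
      }
    })
  rew
}
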