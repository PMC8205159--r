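# Synthetic cohorts with the study's session structure: 2 blocks x 5
# episodes on the canonical environment, block-1 episode start states
# 6, 9, 4, 5, 8, and the silent swap of states 3 and 7 between blocks.
# These simulated cohorts are the package's stand-in for the (undeposited)
# human data.

EPISODE_STARTS <- c(6L, 9L, 4L, 5L, 8L)

steps_matrix <- function(traj) {
  as.matrix(traj[, c("block", "episode", "state", "action", "next_state",
                     "reward")])
}

#' Replay a trajectory through an agent
#'
#' Deterministically replays a recorded trajectory, returning the per-step
#' action probabilities, the summed log-likelihood of the recorded actions,
#' and the per-trial model variables (Surprise, Novelty, NPE, RPE, Reward)
#' plus the per-branch Q-value spreads used by the dominance analysis.
#'
#' @param model Model name.
#' @param params Parameter set.
#' @param traj A trajectory data frame (one row per action) with columns
#'   `block`, `episode`, `state`, `action`, `next_state`, `reward`.
#' @return List with `loglik`, `probs` (n x 4 matrix) and `vars` (n x 7
#'   matrix).
#' @export
replay_trajectory <- function(model, params, traj) {
  out <- cpp_replay(as.numeric(params), unlist(spec_flags(model)),
                    steps_matrix(traj))
  out
}

#' Per-trial model variables of a fitted agent
#'
#' @inheritParams replay_trajectory
#' @return Data frame with the trajectory's context columns and the five
#'   model variables.
#' @export
model_variables <- function(model, params, traj) {
  v <- replay_trajectory(model, params, traj)$vars
  cbind(traj[, c("block", "episode", "step")],
        as.data.frame(v[, c("surprise", "novelty", "npe", "rpe", "reward"),
                        drop = FALSE]))
}

#' Simulate one participant
#'
#' Runs one agent through the full session: block-1 episodes start at
#' states 6, 9, 4, 5, 8; after episode 5 the swap is applied silently and
#' block 2 reuses the same start-state sequence (an assumption; the
#' schedule is configurable). Learning persists across episodes and
#' blocks; actions are sampled from the policy with the seeded generator.
#'
#' @param model Model name.
#' @param params Parameter set.
#' @param env A `surnor_env`.
#' @param seed Integer seed for action sampling.
#' @param step_cap Maximum actions per episode; an episode that reaches the
#'   cap without finding the goal is truncated (its last row does not end
#'   at the goal), which the quit filter uses.
#' @param starts Episode start-state schedule (length 5).
#' @param participant_id Identifier stored in the result.
#' @return Trajectory data frame with columns `participant`, `block`,
#'   `episode`, `step`, `state`, `action`, `next_state`, `reward`.
#' @export
simulate_participant <- function(model, params, env = build_environment(),
                                 seed = 1L, step_cap = 5000L,
                                 starts = EPISODE_STARTS,
                                 participant_id = 1L) {
  stopifnot(step_cap >= 1L, length(starts) == 5L)
  set.seed(as.integer(seed))
  m <- cpp_simulate(as.numeric(params), unlist(spec_flags(model)),
                    displayed_transitions(env, 1L),
                    displayed_transitions(env, 2L),
                    as.integer(starts), as.integer(step_cap))
  df <- as.data.frame(m)
  cbind(participant = participant_id, df)
}

#' Simulate a cohort
#'
#' Deterministic given `(seed, n_agents)`: per-agent seeds are derived from
#' the master seed with [seed_sequence()].
#'
#' @inheritParams simulate_participant
#' @param n_agents Cohort size (200 for posterior-predictive cohorts, 12
#'   for a "simulated participants" set).
#' @return List of trajectory data frames.
#' @export
simulate_cohort <- function(model, params, env = build_environment(),
                            n_agents = 12L, seed = 1L, step_cap = 5000L,
                            starts = EPISODE_STARTS) {
  seeds <- seed_sequence(seed, n_agents)
  lapply(seq_len(n_agents), function(i)
    simulate_participant(model, params, env, seed = seeds[i],
                         step_cap = step_cap, starts = starts,
                         participant_id = i))
}

#' Quit filter for simulated cohorts
#'
#' Discards agents for which any episode took more than `threshold`
#' actions, mirroring the treatment of participants who quit. Reports the
#' discarded fraction with its binomial standard error.
#'
#' @param cohort List of trajectories from [simulate_cohort()].
#' @param threshold Action-count threshold (default 500).
#' @return List with `kept`, `discarded` (lists of trajectories),
#'   `fraction_discarded` and `se`.
#' @export
quit_filter <- function(cohort, threshold = 500L) {
  over <- vapply(cohort, function(tr) {
    any(tapply(tr$step, interaction(tr$block, tr$episode, drop = TRUE),
               max) > threshold)
  }, logical(1))
  n <- length(cohort)
  frac <- mean(over)
  list(kept = cohort[!over], discarded = cohort[over],
       fraction_discarded = frac,
       se = sqrt(frac * (1 - frac) / n))
}

#' Derive reproducible child seeds from a master seed
#'
#' One fixed derivation used everywhere randomness is farmed out (agents,
#' optimizer restarts, Monte-Carlo draws), keeping every run reproducible
#' from a single integer.
#'
#' @param master Master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds below 2^31.
#' @export
seed_sequence <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write / read trajectories as delimited text
#'
#' One step per row, tab-separated, with a `#`-prefixed header line
#' recording the schema.
#'
#' @param cohort List of trajectory data frames.
#' @param path Output file.
#' @export
write_trajectories <- function(cohort, path) {
  df <- do.call(rbind, cohort)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# surnor trajectory table v1", con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  split(df, df$participant)
}
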