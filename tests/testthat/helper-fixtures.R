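# Shared fixtures, built once per test run.

canonical_env <- build_environment()

# Small full-model cohort with default parameters, memoized.
.fixture_cache <- new.env(parent = emptyenv())

fixture_cohort <- function(n = 4L, seed = 7L, model = "SurNoR",
                           params = surnor_params(), step_cap = 501L) {
  key <- paste(model, n, seed, step_cap, digest_params(params), sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_cohort(model, params, canonical_env,
                                             n_agents = n, seed = seed,
                                             step_cap = step_cap)
  .fixture_cache[[key]]
}

digest_params <- function(p) paste(signif(as.numeric(p), 6), collapse = ",")

# Replay a trajectory through the plain-R reference agent, mirroring the
# compiled core; used by the parity test and two-path oracles.
replay_reference <- function(model, params, traj) {
  ag <- build_agent(model, params)
  n <- nrow(traj)
  probs <- matrix(NA_real_, n, 4)
  vars <- matrix(NA_real_, n, 5,
                 dimnames = list(NULL, c("surprise", "novelty", "npe", "rpe",
                                         "reward")))
  loglik <- 0
  cur <- c(-1L, -1L)
  for (i in seq_len(n)) {
    row <- traj[i, ]
    ctx <- c(row$block, row$episode)
    if (!identical(ctx, cur)) {
      ag <- agent_begin_episode(ag, row$state)
      cur <- ctx
    }
    pr <- action_probabilities(ag, row$state, row$block, row$episode)
    probs[i, ] <- pr
    loglik <- loglik + log(pr[row$action])
    st <- agent_step(ag, row$state, row$action, row$next_state, row$reward,
                     row$block, row$episode)
    ag <- st$agent
    vars[i, ] <- st$vars
  }
  list(loglik = loglik, probs = probs, vars = vars, agent = ag)
}
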