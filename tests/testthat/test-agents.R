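test_that("the roster satisfies the printed composition", {
  ro <- model_roster()
  expect_equal(nrow(ro), 15L)  # 13 models + 2 Binary-Novelty controls
  alt <- ro[!ro$name %in% c("SurNoR", "RC") & ro$binary_novelty == "off", ]
  expect_equal(nrow(alt), 11L)
  expect_equal(sum(alt$policy == "MB"), 4L)
  expect_equal(sum(alt$policy == "MF"), 4L)
  expect_equal(sum(alt$policy == "Hyb"), 3L)
  expect_equal(sum(alt$exploration == "novelty"), 5L)
  expect_equal(sum(alt$surprise_mod), 7L)
  expect_equal(sum(alt$exploration == "optimistic_init"), 3L)
  expect_equal(sum(alt$exploration == "uncertainty"), 3L)
})

test_that("free-parameter counts match the study conventions", {
  ro <- model_roster()
  expect_equal(ro$n_free_params[ro$name == "SurNoR"], 18L)
  expect_equal(ro$n_free_params[ro$name == "RC"], 0L)
  expect_equal(ro$n_free_params[ro$name == "SurNoR-BN-threshold"], 19L)
  expect_equal(ro$n_free_params[ro$name == "SurNoR-BN-topn"], 19L)
  expect_true(all(ro$n_free_params <= 19L))
  expect_error(build_agent("NoSuchModel"), "unknown model")
})

test_that("policies are valid distributions with the documented structure", {
  p <- surnor_params()
  # random choice is always uniform
  rc <- build_agent("RC", p)
  expect_equal(action_probabilities(rc, 5L, 1L, 1L), rep(0.25, 4))
  # a fresh agent has equal combined values: uniform softmax
  ag <- build_agent("SurNoR", p)
  expect_equal(action_probabilities(ag, 1L, 2L, 3L), rep(0.25, 4))
  # optimistic initialization puts the optimistic value in the reward tables
  oi <- build_agent("MF+OI", surnor_params(q_oi = 0.8))
  expect_true(all(oi$q_mf_r == 0.8))
  # scaling values sharpens toward the argmax
  ag$q_mf_r[2, ] <- c(0.5, 0.1, 0.2, 0.1)
  pr1 <- action_probabilities(ag, 2L, 1L, 2L)
  ag2 <- ag
  ag2$q_mf_r[2, ] <- ag$q_mf_r[2, ] * 50
  pr2 <- action_probabilities(ag2, 2L, 1L, 2L)
  expect_gt(pr2[1], pr1[1])
  expect_gt(pr2[1], 0.99)
})

test_that("novelty values enter the policy only in first episodes", {
  p <- surnor_params()
  tr <- fixture_cohort(1)[[1]]
  ag <- replay_reference("SurNoR", p, tr[tr$block == 1 & tr$episode == 1, ])$agent
  for (ep in c(2L, 5L)) {
    base <- action_probabilities(ag, 2L, 1L, ep)
    mod <- ag
    mod$q_mf_n[2, ] <- mod$q_mf_n[2, ] + c(5, -3, 2, 0)
    mod$q_mb_n[2, ] <- mod$q_mb_n[2, ] * 2
    expect_equal(action_probabilities(mod, 2L, 1L, ep), base)
  }
  # but they do matter in episode 1
  mod <- ag
  mod$q_mb_n[2, ] <- mod$q_mb_n[2, ] + c(50, 0, 0, 0)
  expect_false(isTRUE(all.equal(action_probabilities(mod, 2L, 1L, 1L),
                                action_probabilities(ag, 2L, 1L, 1L))))
})

test_that("pure model-free agents ignore their world-model for action choice", {
  p <- surnor_params()
  tr <- fixture_cohort(1)[[1]]
  sub <- tr[seq_len(40), ]
  ref <- replay_reference("MF+S+N", p, sub)
  ag <- ref$agent
  expect_gt(sum(ag$pc), 0)  # the world-model is still maintained (for surprise)
  mod <- ag
  mod$q_mb_r <- mod$q_mb_r + 5
  mod$q_mb_n <- mod$q_mb_n - 2
  for (s in 1:7)
    expect_equal(action_probabilities(mod, s, 1L, 1L),
                 action_probabilities(ag, s, 1L, 1L))
})

test_that("the uncertainty-seeking intrinsic reward is the surprisal of the transition", {
  # a first-ever transition under the uniform prior has surprise 1, hence
  # surprisal 0; the fresh-agent NPE then reduces to q_n0 * (lambda_n - 1)
  p <- surnor_params(q_n0 = 2, lambda_n = 0.9)
  ag <- build_agent("MF+S+U", p)
  ag <- agent_begin_episode(ag, 6L)
  st <- agent_step(ag, 6L, 1L, 9L, 0L, 1L, 1L)
  expect_equal(st$vars[["surprise"]], 1)
  expect_equal(st$vars[["npe"]], 2 * (0.9 - 1))
})

test_that("compiled replay matches the plain-R reference bit-for-bit", {
  p <- surnor_params()
  tr <- fixture_cohort(2)[[1]]
  # span both blocks: take a slice around the block boundary
  b1 <- which(tr$block == 1)
  b2 <- which(tr$block == 2)
  idx <- c(utils::tail(b1, 150), utils::head(b2, 150))
  sub <- tr[idx, ]
  for (model in c("SurNoR", "MF+S+N", "Hyb+N", "MB+S+U", "SurNoR-BN-topn")) {
    cppr <- replay_trajectory(model, p, sub)
    ref <- replay_reference(model, p, sub)
    expect_equal(cppr$loglik, ref$loglik, tolerance = 1e-8)
    expect_equal(max(abs(cppr$probs - ref$probs)), 0, tolerance = 1e-8)
    expect_equal(max(abs(cppr$vars[, 1:5] - ref$vars)), 0, tolerance = 1e-8)
  }
})

test_that("agents are deterministic functions of history", {
  p <- surnor_params()
  c1 <- simulate_cohort("SurNoR", p, canonical_env, n_agents = 2, seed = 11,
                        step_cap = 300)
  c2 <- simulate_cohort("SurNoR", p, canonical_env, n_agents = 2, seed = 11,
                        step_cap = 300)
  expect_identical(c1, c2)
  r1 <- replay_trajectory("SurNoR", p, c1[[1]])
  r2 <- replay_trajectory("SurNoR", p, c1[[1]])
  expect_identical(r1, r2)
})

test_that("simulated full-model cohorts reproduce the adaptation profile", {
  p <- surnor_params()
  coh <- fixture_cohort(8)
  el <- episode_lengths(coh, drop_truncated = FALSE)$per_episode
  m <- tapply(el$n_actions, list(el$block, el$episode), mean)
  # episode 1 of block 2 shorter than episode 1 of block 1 on average
  expect_lt(m["2", "1"], m["1", "1"])
  # later episodes far shorter than first episodes (learning)
  expect_lt(mean(m["1", 3:5]), m["1", "1"] / 3)
  expect_lt(mean(m["2", 3:5]), m["2", "1"] / 3)
  # escape latency decreases with trap visits (first vs last third)
  lat <- escape_latency(coh, block = 1, episode = 1)
  k <- nrow(lat)
  expect_gt(mean(lat$median[1:3]), mean(lat$median[(k - 2):k]))
  # progress at unchanged states is retained right after the swap
  pg <- progress_score(coh, canonical_env, states = c(1L, 2L, 4L),
                       block = 2, episode = 1)
  early <- pg[pg$visit <= 2, ]
  expect_gt(mean(early$mean), 0.25)
})
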