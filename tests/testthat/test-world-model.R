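test_that("transition probabilities follow the pseudo-count rule", {
  pc <- pseudo_count_table()
  expect_equal(transition_probability(pc, 0.1, 1L, 1L, 5L), 1 / 11)
  pc[1, 1, 5] <- 1
  expect_equal(transition_probability(pc, 0.1, 1L, 1L, 5L), 1.1 / 2.1)
  # normalization over successors for random tables
  set.seed(4)
  pc[, , ] <- rexp(length(pc))
  for (s in c(1L, 6L, 10L)) for (a in 1:4)
    expect_equal(sum(vapply(1:11, function(sn)
      transition_probability(pc, 0.3, s, a, sn), 0)), 1)
})

test_that("Bayes-Factor surprise is the reset-to-model probability ratio", {
  expect_equal(bayes_factor_surprise(1 / 11), 1)
  expect_equal(bayes_factor_surprise(1), 1 / 11)
  expect_error(bayes_factor_surprise(0), "positive")
  # equivalent formulation through the state prediction error
  p <- c(0.05, 0.3, 0.9)
  spe <- 1 - p
  expect_equal(bayes_factor_surprise(p), (1 / 11) / (1 - spe))
})

test_that("the adaptation factor interpolates between 0 and 1", {
  expect_equal(adaptation_factor(0, 5), 0)
  expect_equal(adaptation_factor(3, 0), 0)
  expect_equal(adaptation_factor(1, 1), 0.5)
  expect_gt(adaptation_factor(1e9, 0.1), 1 - 1e-7)
  s <- seq(0, 10, by = 0.5)
  expect_true(all(diff(adaptation_factor(s, 0.7)) > 0))
})

test_that("the SMiLe update increments, resets, or interpolates per gamma", {
  pc <- pseudo_count_table()
  pc[2, 3, ] <- c(1, 2, 0, 4, 0, 0, 0, 0, 0, 0, 0)
  # gamma = 0: plain increment of the observed successor
  up0 <- smile_update(pc, 0, 2L, 3L, 4L)
  expect_equal(up0[2, 3, 4], 5)
  expect_equal(up0[2, 3, -4], pc[2, 3, -4])
  # gamma = 1: the row resets and the observation counts as the first one
  up1 <- smile_update(pc, 1, 2L, 3L, 4L)
  expect_equal(up1[2, 3, ], c(0, 0, 0, 1, rep(0, 7)))
  # gamma = 0.5 with a prior pseudo-count of 4 at the observed successor
  up5 <- smile_update(pc, 0.5, 2L, 3L, 4L)
  expect_equal(up5[2, 3, 4], 0.5 * 4 + 1)
  # only the active row changes
  pc[5, 1, 9] <- 2
  up <- smile_update(pc, 0.7, 2L, 3L, 4L)
  expect_equal(up[5, 1, ], pc[5, 1, ])
  # non-negativity for arbitrary gamma
  set.seed(5)
  for (k in 1:20) {
    g <- runif(1)
    pc <- smile_update(pc, g, sample(10, 1), sample(4, 1), sample(11, 1))
    expect_true(all(pc >= 0))
  }
})

test_that("repeated unsurprising observations drive the model toward certainty", {
  pc <- pseudo_count_table()
  eps <- 0.05
  probs <- numeric(30)
  for (T in 1:30) {
    pc <- smile_update(pc, 0, 4L, 2L, 5L)
    probs[T] <- transition_probability(pc, eps, 4L, 2L, 5L)
    expect_equal(probs[T], (T + eps) / (T + 11 * eps))
  }
  expect_true(all(diff(probs) > 0))
})

test_that("replaying a trained model against swapped transitions peaks surprise at the swap", {
  p <- surnor_params()
  tr <- fixture_cohort(2)[[1]]
  v <- replay_trajectory("SurNoR", p, tr)$vars
  b2e1 <- tr$block == 2 & tr$episode == 1
  sur <- v[b2e1, "surprise"]
  touching_swap <- tr$state[b2e1] %in% c(3L, 7L) | tr$next_state[b2e1] %in% c(3L, 7L)
  # every strongly surprising transition involves a swapped state
  expect_true(all(touching_swap[sur > 10]))
  expect_gt(max(sur), 10)
})

test_that("Bellman solutions are exact: trivial cases and the learned chain", {
  pc <- pseudo_count_table()
  q0 <- solve_mb_values(pc, 0.1, rep(0, 11), 0.9)
  expect_equal(q0, matrix(0, 10, 4))
  # a deterministically learned chain backs up the goal reward geometrically
  env <- canonical_env
  for (s in 1:7) {
    good <- which(env$roles[s, ] == "good")
    for (k in 1:500) pc <- smile_update(pc, 0, s, good, env$trans[s, good])
  }
  lam <- 0.9
  rew <- c(rep(0, 10), 1)
  q <- solve_mb_values(pc, 1e-6, rew, lam)
  expect_equal(q[7, which(env$roles[7, ] == "good")], 1, tolerance = 1e-3)
  expect_equal(q[6, which(env$roles[6, ] == "good")], lam, tolerance = 1e-3)
})

test_that("prioritized sweeping agrees with value iteration on random MDPs", {
  set.seed(6)
  for (k in 1:50) {
    pc <- pseudo_count_table()
    n_obs <- sample(20:60, 1)
    for (i in seq_len(n_obs))
      pc <- smile_update(pc, runif(1, 0, 0.3), sample(10, 1), sample(4, 1),
                         sample(11, 1))
    rew <- rnorm(11)
    disc <- runif(1, 0.5, 0.95)
    eps <- runif(1, 0.01, 0.5)
    q_vi <- solve_mb_values(pc, eps, rew, disc, tol = 1e-12)
    q_ps <- solve_mb_values(pc, eps, rew, disc,
                            method = "prioritized_sweeping", t_ps = 5000L,
                            tol = 1e-12)
    expect_lt(max(abs(q_vi - q_ps)), 1e-6)
  }
})
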