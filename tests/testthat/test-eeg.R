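sim_vars <- function(n = 400, seed = 1) {
  set.seed(seed)
  data.frame(block = rep(1:2, each = n / 2),
             episode = rep(rep(1:5, each = n / 10), 2),
             step = seq_len(n),
             surprise = rexp(n), novelty = runif(n, 0, 3), npe = rnorm(n),
             rpe = rnorm(n) + 0.8 * (r <- rbinom(n, 1, 0.1)), reward = r)
}

test_that("regressors are normalized, decorrelated combinations", {
  vars <- sim_vars()
  X <- build_regressors(vars)
  expect_equal(colnames(X), c("surprise_perp", "novelty_perp", "npe_perp",
                              "r_plus", "r_minus"))
  expect_equal(unname(colMeans(X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # R+ and R- are uncorrelated; each perp column orthogonal to both
  expect_lt(abs(cor(X[, "r_plus"], X[, "r_minus"])), 1e-10)
  for (nm in c("surprise_perp", "novelty_perp", "npe_perp")) {
    expect_lt(abs(cor(X[, nm], X[, "r_plus"])), 1e-10)
    expect_lt(abs(cor(X[, nm], X[, "r_minus"])), 1e-10)
  }
  # perp columns stay close to their raw sources
  raw <- attr(X, "raw")
  for (nm in c("surprise", "novelty", "npe"))
    expect_gt(cor(X[, paste0(nm, "_perp")], raw[, nm]), 0.5)
  # a variable already uncorrelated with reward and RPE is nearly unchanged
  vars2 <- vars
  vars2$surprise <- rnorm(nrow(vars))
  X2 <- build_regressors(vars2)
  expect_gt(cor(X2[, "surprise_perp"], scale(vars2$surprise)), 0.99)
})

test_that("degenerate inputs are rejected with the offending column named", {
  vars <- sim_vars()
  vars$novelty <- 1
  expect_error(build_regressors(vars), "novelty")
  vars <- sim_vars()
  vars$rpe <- vars$reward  # perfectly correlated: R- degenerates
  expect_error(build_regressors(vars), "R-")
  expect_error(build_regressors(sim_vars()[1:4, ]), "6 trials")
})

test_that("per-timepoint regression recovers planted coefficients", {
  vars <- sim_vars(n = 300, seed = 2)
  X <- build_regressors(vars)
  b <- erp_peak_profile(amplitude = 0.8)
  # noiseless: perfect fit at every time point
  Y0 <- synth_erp(X, b, noise_sd = 0, seed = 3)
  fit0 <- encode_mlr(X, Y0)
  active <- which(b[1, ] > 1e-6)
  expect_true(all(fit0$adj_r_squared[active] > 1 - 1e-8))
  # with noise: planted coefficients recovered within OLS confidence bounds
  Y <- synth_erp(X, b, noise_sd = 1, seed = 4)
  fit <- encode_mlr(X, Y)
  peak <- which.max(b["surprise_perp", ])
  yn <- scale(Y[, peak])
  ols <- stats::lm(yn ~ X)
  ci <- stats::confint(ols)
  expect_true(all(ci[-1, 1] <= coef(ols)[-1] & coef(ols)[-1] <= ci[-1, 2]))
  # pure noise: mean adjusted R-squared near zero across simulations
  r2 <- replicate(20, {
    Yn <- matrix(rnorm(nrow(X) * 65), nrow(X), 65)
    mean(encode_mlr(X, Yn)$adj_r_squared)
  })
  expect_lt(abs(mean(r2)), 0.01)
  expect_error(encode_mlr(X[1:4, ], Y0[1:4, ]), "trials")
})

test_that("noise level degrades encoding power monotonically, reproducibly", {
  vars <- sim_vars(n = 200, seed = 5)
  X <- build_regressors(vars)
  b <- erp_peak_profile(amplitude = 1)
  mean_r2 <- vapply(c(0.5, 1, 2, 4), function(sd_) {
    mean(vapply(1:5, function(s)
      mean(encode_mlr(X, synth_erp(X, b, noise_sd = sd_, seed = s))$adj_r_squared),
      0))
  }, 0)
  expect_true(all(diff(mean_r2) < 0))
  expect_identical(synth_erp(X, b, 1, seed = 9), synth_erp(X, b, 1, seed = 9))
  expect_error(synth_erp(X, b[, 1:10], 1, 1), "65 time columns")
})

test_that("window statistics find planted windows and nothing under the null", {
  n_sub <- 6
  b <- erp_peak_profile(amplitude = 0.6)
  fits <- lapply(1:n_sub, function(s) {
    vars <- sim_vars(n = 250, seed = 100 + s)
    X <- build_regressors(vars)
    encode_mlr(X, synth_erp(X, b, noise_sd = 1.5, seed = 200 + s))
  })
  ws <- window_stats(fits)
  expect_gt(length(ws$windows), 0)
  peak_idx <- which.max(b["surprise_perp", ])
  in_win <- any(vapply(ws$windows, function(w) peak_idx %in% w, logical(1)))
  expect_true(in_win)
  wc <- ws$window_coefficients
  planted <- wc[wc$regressor %in% c("surprise_perp", "novelty_perp",
                                    "npe_perp", "r_plus") &
                  vapply(wc$window, function(k) peak_idx %in% ws$windows[[k]],
                         logical(1)), ]
  expect_true(all(planted$mean > 0))
  expect_true(any(planted$significant))
  # null data: no significant encoding anywhere
  fits0 <- lapply(1:n_sub, function(s) {
    vars <- sim_vars(n = 250, seed = 300 + s)
    X <- build_regressors(vars)
    encode_mlr(X, matrix(rnorm(250 * 65), 250, 65))
  })
  ws0 <- window_stats(fits0)
  expect_equal(length(ws0$windows), 0L)
  expect_error(window_stats(fits[1]), "2 participants")
  # contiguous runs group into windows; gaps split them
  expect_equal(surnor:::group_windows(c(1L, 2L, 3L, 7L, 8L)),
               list(1:3, 7:8))
  # splitting preserves coverage: windows partition the significant points
  expect_equal(sort(unlist(ws$windows)), which(ws$power$significant))
})

test_that("grand correlations are energy-invariant and apply the RPE exclusion", {
  n_sub <- 3
  vars_list <- lapply(1:n_sub, function(s) sim_vars(n = 200, seed = 400 + s))
  erp_list <- lapply(1:n_sub, function(s) {
    X <- build_regressors(vars_list[[s]])
    synth_erp(X, erp_peak_profile(amplitude = 0.7), noise_sd = 1,
              seed = 500 + s)
  })
  gc1 <- grand_correlation(vars_list, erp_list)
  # rescaling one participant's ERPs leaves the pooled result unchanged
  erp_list2 <- erp_list
  erp_list2[[2]] <- erp_list2[[2]] * 10
  gc2 <- grand_correlation(vars_list, erp_list2)
  expect_equal(gc1$r, gc2$r, tolerance = 1e-12)
  # the RPE rows exclude exactly the block-1 episode-1 trials
  n_excl <- sum(vars_list[[1]]$block == 1 & vars_list[[1]]$episode == 1) * 1 +
    sum(vars_list[[2]]$block == 1 & vars_list[[2]]$episode == 1) +
    sum(vars_list[[3]]$block == 1 & vars_list[[3]]$episode == 1)
  n_total <- sum(vapply(vars_list, nrow, integer(1)))
  expect_equal(unique(gc1$n[gc1$variable == "rpe"]), n_total - n_excl)
  expect_equal(unique(gc1$n[gc1$variable == "surprise"]), n_total)
  # a planted positive-signal variable correlates positively at the peak
  peak <- which.max(erp_peak_profile()[1, ])
  sur <- gc1[gc1$variable == "surprise", ]
  expect_gt(sur$r[peak], 0)
  expect_true(sur$significant[peak])
})
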