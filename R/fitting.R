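# Likelihood-based fitting and model comparison: coordinate-ascent maximum
# likelihood with grid search per coordinate, 3-fold cross-validated
# held-out log-likelihood as model evidence, and accuracy/entropy/dominance
# summaries of a fitted policy.

#' Log-likelihood of recorded action sequences
#'
#' Sum over steps of the log probability that the model's policy assigns to
#' the recorded action, replaying learning deterministically through the
#' trajectory. For a cohort, the participant log-likelihoods add.
#'
#' @param model Model name.
#' @param params Parameter set.
#' @param trajectories A trajectory data frame or a list of them.
#' @return Total log-likelihood (scalar).
#' @export
sequence_log_likelihood <- function(model, params, trajectories) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  sum(vapply(trajectories, function(tr)
    replay_trajectory(model, params, tr)$loglik, numeric(1)))
}

#' Default coordinate-ascent search grids
#'
#' Grid specifications per parameter (bounds and spacing are a documented
#' package default, overridable). Parameters not listed in a grid are held
#' at their values in the supplied parameter set; a single-value grid fixes
#' a parameter explicitly. The `"coarse"` preset searches fewer values over
#' the same bounds and is used by the scaled-down recovery analyses.
#'
#' @param preset `"default"` or `"coarse"`.
#' @param model Optional model name; if given, grids are restricted to that
#'   model's free parameters.
#' @return Named list of numeric grids.
#' @export
surnor_grids <- function(preset = c("default", "coarse"), model = NULL) {
  preset <- match.arg(preset)
  g <- if (preset == "default") list(
    epsilon = c(0.001, 0.01, 0.1, 1),
    m = c(0, 0.05, 0.2, 1, 5),
    beta_1 = c(5, 10, 25, 60, 120),
    beta_2 = c(5, 10, 25, 60, 120),
    beta_n1 = c(0, 0.001, 0.003, 0.01, 0.03, 0.1),
    beta_n2 = c(0, 0.001, 0.003, 0.01, 0.03, 0.1),
    lambda_r = c(0.5, 0.8, 0.9, 0.95, 0.99),
    lambda_n = c(0.5, 0.8, 0.9, 0.95, 0.99),
    mu_r = c(0, 0.3, 0.6, 0.8, 0.95),
    mu_n = c(0, 0.3, 0.6, 0.8, 0.95),
    rho_b = c(0.01, 0.03, 0.06, 0.1, 0.2, 0.4),
    delta_rho = c(0, 0.1, 0.3, 0.5, 1),
    q_n0 = c(0, 4, 12, 24, 36),
    omega_0 = c(0, 0.2, 0.4, 0.6, 0.8, 1),
    omega_11 = c(0, 0.25, 0.5, 0.75, 1),
    omega_12 = c(0, 0.25, 0.5, 0.75, 1),
    omega_scale = c(0.25, 0.5, 1, 2, 4),
    gamma_leak = c(0, 0.01, 0.05, 0.2),
    q_oi = c(0.1, 0.5, 1, 3),
    bn_theta = c(2, 5, 10, 20),
    bn_n = c(1, 2, 3, 4))
  else list(
    epsilon = c(0.01, 0.3),
    m = c(0.02, 0.2, 2),
    beta_1 = c(10, 25, 60),
    beta_2 = c(10, 25, 60),
    beta_n1 = c(0, 0.003, 0.03),
    beta_n2 = c(0, 0.01, 0.05),
    lambda_r = c(0.8, 0.95),
    lambda_n = c(0.8, 0.95),
    mu_r = c(0.3, 0.8),
    mu_n = c(0.3, 0.8),
    rho_b = c(0.03, 0.06, 0.15),
    delta_rho = c(0, 0.5, 1),
    q_n0 = c(4, 24),
    omega_0 = c(0.2, 0.5, 0.8),
    omega_11 = c(0.25, 0.75),
    omega_12 = c(0.25, 0.75),
    omega_scale = c(0.5, 1, 2),
    gamma_leak = c(0, 0.05),
    q_oi = c(0.5, 2),
    bn_theta = c(5, 15),
    bn_n = c(2, 4))
  if (!is.null(model)) g <- g[intersect(names(g), free_parameters(model))]
  g
}

#' Fit a model to trajectories by coordinate ascent
#'
#' Maximizes the action-sequence log-likelihood by cycling through the
#' parameters, grid-searching each while holding the others fixed, until a
#' full sweep yields no improvement (absolute improvement below `tol`);
#' the best result over `n_restarts` random grid initializations is kept.
#'
#' @param model Model name.
#' @param trajectories Trajectory data frame or list of them.
#' @param grids Named list of per-parameter grids (see [surnor_grids()]).
#' @param params Base parameter set supplying values for parameters without
#'   a grid.
#' @param n_restarts Number of random initial points (study convention: 25;
#'   reduce for scaled-down analyses).
#' @param seed Seed controlling restart initialization.
#' @param max_sweeps Safety cap on coordinate sweeps per restart.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return Object of class `surnor_fit`.
#' @export
surnor_fit <- function(model, trajectories, grids = surnor_grids(model = model),
                       params = surnor_params(), n_restarts = 25L, seed = 1L,
                       max_sweeps = 20L, tol = 1e-6) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  grids <- grids[intersect(names(grids), free_parameters(model))]
  if (length(grids) && any(vapply(grids, length, integer(1)) == 0L))
    stop("empty grid supplied")
  if (model == "RC" || length(grids) == 0L) {
    ll <- sequence_log_likelihood(model, params, trajectories)
    return(new_surnor_fit(model, params, ll, trajectories, restart = 0L,
                          log = data.frame()))
  }
  ll_fun <- function(p) sequence_log_likelihood(model, p, trajectories)
  seeds <- seed_sequence(seed, n_restarts)
  best <- NULL
  logs <- list()
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    p <- unclass(params)
    for (nm in names(grids)) p[nm] <- sample(grids[[nm]], 1L)
    ll <- ll_fun(p)
    for (sweep in seq_len(max_sweeps)) {
      ll_before <- ll
      for (nm in names(grids)) {
        vals <- grids[[nm]]
        lls <- vapply(vals, function(v) { q <- p; q[nm] <- v; ll_fun(q) },
                      numeric(1))
        k <- which.max(lls)  # ties: first grid point
        p[nm] <- vals[k]
        ll <- lls[k]
      }
      if (ll - ll_before < tol) break
    }
    logs[[r]] <- data.frame(restart = r, loglik = ll, sweeps = sweep)
    if (is.null(best) || ll > best$ll) best <- list(p = p, ll = ll, restart = r)
  }
  new_surnor_fit(model, structure(best$p, class = "surnor_params"), best$ll,
                 trajectories, restart = best$restart,
                 log = do.call(rbind, logs))
}

new_surnor_fit <- function(model, params, loglik, trajectories, restart, log) {
  per <- vapply(trajectories, function(tr)
    replay_trajectory(model, params, tr)$loglik, numeric(1))
  structure(list(model = model, params = params, loglik = loglik,
                 per_participant = per, n_actions = sum(vapply(trajectories, nrow, integer(1))),
                 restart = restart, convergence = log),
            class = "surnor_fit")
}

#' @export
print.surnor_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  cat("Log-likelihood:", format(x$loglik, digits = 6), "over", x$n_actions,
      "actions (", length(x$per_participant), "participants )\n")
  if (x$restart > 0) cat("Best restart:", x$restart, "\n")
  invisible(x)
}

#' @export
coef.surnor_fit <- function(object, ...) {
  p <- unclass(object$params)
  p[free_parameters(object$model)]
}

#' @export
logLik.surnor_fit <- function(object, ...) {
  structure(object$loglik, df = length(free_parameters(object$model)),
            class = "logLik")
}

#' @export
summary.surnor_fit <- function(object, ...) {
  print(object)
  cat("\nFitted free parameters:\n")
  print(round(coef(object), 4))
  invisible(object)
}

make_folds <- function(n, k = 3L) {
  if (n %% k != 0L)
    warning("cohort size ", n, " is not divisible into ", k,
            " equal folds; folds rebuilt proportionally")
  split(seq_len(n), rep(seq_len(k), each = ceiling(n / k))[seq_len(n)])
}

#' Cross-validated model evidence
#'
#' For each participant, the held-out log-likelihood under parameters
#' fitted (by [surnor_fit()]) to the other two of three fixed folds; the
#' whole procedure is repeated `n_repeats` times with re-randomized
#' optimizer restarts (fold assignment stays fixed) to quantify optimizer
#' noise. The per-participant evidence averaged over repeats feeds the
#' random-effects model selection; differences in summed evidence greater
#' than 3 (10) are conventionally read as (strongly) significant.
#'
#' @param models Character vector of model names.
#' @param cohort List of trajectories (12 for the study layout: 3 folds of
#'   4; other sizes are split proportionally with a warning).
#' @param grids_preset Grid preset for the inner fits.
#' @param n_restarts,n_repeats Optimizer restarts per fit and process
#'   repeats.
#' @param params Base parameter set.
#' @param seed Master seed.
#' @param grids Optional named list of grids overriding the preset; for
#'   each model it is restricted to that model's free parameters
#'   (parameters without a grid stay at their `params` values).
#' @return Object of class `surnor_evidence`: contains `table` (data frame
#'   participant x model x repeat), `mean_evidence` (participant x model
#'   matrix averaged over repeats) and `summed` (per model, with the
#'   between-repeat standard error).
#' @export
crossval_evidence <- function(models, cohort, grids_preset = "coarse",
                              n_restarts = 3L, n_repeats = 1L,
                              params = surnor_params(), seed = 1L,
                              grids = NULL) {
  n <- length(cohort)
  folds <- make_folds(n, 3L)
  rep_seeds <- seed_sequence(seed, n_repeats)
  rows <- list()
  for (mod in models) {
    for (r in seq_len(n_repeats)) {
      ev <- numeric(n)
      for (f in seq_along(folds)) {
        held <- folds[[f]]
        train <- setdiff(seq_len(n), held)
        mod_grids <- if (is.null(grids))
          surnor_grids(grids_preset, model = mod)
        else grids[intersect(names(grids), free_parameters(mod))]
        fit <- surnor_fit(mod, cohort[train], grids = mod_grids,
                          params = params, n_restarts = n_restarts,
                          seed = rep_seeds[r] + f)
        ev[held] <- vapply(cohort[held], function(tr)
          replay_trajectory(mod, fit$params, tr)$loglik, numeric(1))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(participant = seq_len(n), model = mod, repetition = r,
                   log_evidence = ev)
    }
  }
  tab <- do.call(rbind, rows)
  mean_ev <- with(tab, tapply(log_evidence, list(participant, model), mean))
  mean_ev <- mean_ev[, models, drop = FALSE]
  summed_rep <- with(tab, tapply(log_evidence, list(model, repetition), sum))
  summed <- data.frame(model = models,
                       log_evidence = colSums(mean_ev),
                       se = apply(summed_rep[models, , drop = FALSE], 1, function(v)
                         if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_))
  structure(list(table = tab, mean_evidence = mean_ev, summed = summed,
                 folds = folds),
            class = "surnor_evidence")
}

#' @export
print.surnor_evidence <- function(x, ...) {
  cat("Cross-validated log-evidence (summed over participants):\n")
  s <- x$summed
  if ("RC" %in% s$model)
    s$vs_RC <- s$log_evidence - s$log_evidence[s$model == "RC"]
  print(s, row.names = FALSE)
  invisible(x)
}

#' Accuracy of action prediction with fractional tie counting
#'
#' A trial counts 1 if the taken action is the unique most probable action
#' under the policy, 1/n if it ties with n-1 other actions at maximal
#' probability, and 0 otherwise; the result is the mean over trials. The
#' random-choice policy scores exactly 25%.
#'
#' @inheritParams sequence_log_likelihood
#' @param tie_tol Numerical tolerance for probability ties.
#' @return Fraction in \[0, 1\].
#' @export
accuracy_rate <- function(model, params, trajectories, tie_tol = 1e-9) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  num <- 0; den <- 0
  for (tr in trajectories) {
    pr <- replay_trajectory(model, params, tr)$probs
    taken <- tr$action
    for (i in seq_len(nrow(pr))) {
      mx <- max(pr[i, ])
      top <- which(pr[i, ] >= mx - tie_tol)
      num <- num + if (taken[i] %in% top) 1 / length(top) else 0
      den <- den + 1
    }
  }
  num / den
}

#' Mean policy entropy
#'
#' Shannon entropy (nats) of the 4-action choice distribution per trial,
#' averaged over all trials or per episode. Maximum log 4 (random choice),
#' 0 for a deterministic policy.
#'
#' @inheritParams sequence_log_likelihood
#' @param per_episode If `TRUE`, return a data frame of per-episode means.
#' @export
policy_entropy <- function(model, params, trajectories, per_episode = FALSE) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  ent_tr <- lapply(trajectories, function(tr) {
    pr <- replay_trajectory(model, params, tr)$probs
    h <- -rowSums(ifelse(pr > 0, pr * log(pr), 0))
    data.frame(block = tr$block, episode = tr$episode, entropy = h)
  })
  all <- do.call(rbind, ent_tr)
  if (!per_episode) return(mean(all$entropy))
  agg <- aggregate(entropy ~ block + episode, data = all, FUN = mean)
  agg[order(agg$block, agg$episode), ]
}

#' Dominance of the model-free branch in the hybrid policy
#'
#' The effective weight of a branch is its policy weight times the trial
#' average of the spread (best minus worst action value) of that branch's
#' Q-values; the dominance is the model-free over the model-based effective
#' weight. Values above 1 mean model-free control of action selection.
#'
#' @inheritParams sequence_log_likelihood
#' @param groups How to group episodes: the default forms four groups
#'   (episode 1 vs episodes 2-5, per block).
#' @return Data frame with group labels, effective weights and dominance;
#'   a zero model-based effective weight is reported as `Inf` with
#'   `flagged = TRUE`.
#' @export
branch_dominance <- function(model, params, trajectories, groups = NULL) {
  spec <- model_spec(model)
  if (spec$policy != "Hyb") stop("dominance is defined for hybrid policies")
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  vars <- do.call(rbind, lapply(trajectories, function(tr) {
    v <- replay_trajectory(model, params, tr)$vars
    data.frame(block = tr$block, episode = tr$episode,
               dq_mf = v[, "dq_mf"], dq_mb = v[, "dq_mb"])
  }))
  if (is.null(groups))
    vars$group <- paste0("block", vars$block,
                         ifelse(vars$episode == 1L, "_ep1", "_ep2-5"))
  else vars$group <- groups(vars$block, vars$episode)
  w_mf <- 1 - params[["omega_0"]]
  w_mb <- params[["omega_0"]]
  out <- do.call(rbind, lapply(split(vars, vars$group), function(g) {
    eff_mf <- w_mf * mean(g$dq_mf)
    eff_mb <- w_mb * mean(g$dq_mb)
    data.frame(group = g$group[1], eff_mf = eff_mf, eff_mb = eff_mb,
               dominance = if (eff_mb == 0) Inf else eff_mf / eff_mb,
               flagged = eff_mb == 0)
  }))
  rownames(out) <- NULL
  out[order(out$group), ]
}

#' Parameter recovery analysis
#'
#' Fits a model to a cohort generated by known parameters and correlates
#' the per-trial model variables (Surprise, NPE, RPE; Novelty depends on
#' the trajectory only) extracted under the recovered parameters with those
#' extracted under the generating parameters, per participant.
#'
#' @param model Model name (generating and fitted).
#' @param true_params Generating parameter set.
#' @param cohort Cohort simulated from `true_params`.
#' @param ... Passed to [surnor_fit()].
#' @return List with `fit`, and `correlations`: a data frame of mean (over
#'   participants) correlation per model variable.
#' @export
recover_parameters <- function(model, true_params, cohort, ...) {
  fit <- surnor_fit(model, cohort, ...)
  vars <- c("surprise", "novelty", "npe", "rpe")
  cors <- vapply(cohort, function(tr) {
    v_true <- replay_trajectory(model, true_params, tr)$vars
    v_fit <- replay_trajectory(model, fit$params, tr)$vars
    vapply(vars, function(nm) {
      if (stats::sd(v_true[, nm]) == 0 || stats::sd(v_fit[, nm]) == 0)
        return(NA_real_)
      stats::cor(v_true[, nm], v_fit[, nm])
    }, numeric(1))
  }, numeric(length(vars)))
  list(fit = fit,
       correlations = data.frame(variable = vars,
                                 mean_correlation = rowMeans(cors, na.rm = TRUE)))
}

#' Model recovery analysis
#'
#' Simulates cohorts from a generating model, runs cross-validated evidence
#' for a set of candidate models, and reports per cohort which candidate
#' wins the summed evidence and the posterior model probability.
#'
#' @param generating Generating model name.
#' @param candidates Candidate model names (must include `generating`).
#' @param params Generating parameters.
#' @param env Environment.
#' @param n_cohorts Number of independent cohorts.
#' @param n_agents Cohort size.
#' @param seed Master seed.
#' @param ... Passed to [crossval_evidence()].
#' @return Data frame per cohort: winner by summed evidence, winner by
#'   posterior probability, plus the evidence objects in `attr(, "detail")`.
#' @export
recover_model <- function(generating = "SurNoR",
                          candidates = c("SurNoR", "MF+S+N", "Hyb+S+U", "Hyb+N", "RC"),
                          params = surnor_params(), env = build_environment(),
                          n_cohorts = 3L, n_agents = 12L, seed = 1L, ...) {
  stopifnot(generating %in% candidates)
  cohort_seeds <- seed_sequence(seed, n_cohorts)
  detail <- list()
  rows <- list()
  for (i in seq_len(n_cohorts)) {
    cohort <- simulate_cohort(generating, params, env, n_agents = n_agents,
                              seed = cohort_seeds[i], step_cap = 501L)
    ev <- crossval_evidence(candidates, cohort, seed = cohort_seeds[i], ...)
    bms <- bms_random_effects(ev$mean_evidence, seed = cohort_seeds[i])
    detail[[i]] <- list(evidence = ev, bms = bms)
    rows[[i]] <- data.frame(
      cohort = i,
      winner_evidence = ev$summed$model[which.max(ev$summed$log_evidence)],
      winner_posterior = colnames(ev$mean_evidence)[which.max(bms$posterior_prob)])
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  out
}
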