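# Random-effects Bayesian model selection over per-participant log-evidence:
# variational estimation of the Dirichlet posterior over population model
# frequencies, exceedance probabilities by Monte-Carlo sampling of that
# posterior, and the protected exceedance probability obtained by blending
# with the Bayesian omnibus risk (the posterior probability that model
# frequencies are all equal).

#' Random-effects Bayesian model selection
#'
#' Treats the model identity of each participant as drawn from an unknown
#' population distribution with a Dirichlet prior (concentration 1/K per
#' model, so the prior carries the weight of a single participant) and
#' estimates the Dirichlet posterior by variational Bayes. Exceedance
#' probabilities — the probability that a model is the most frequent in the
#' population — are computed by Monte-Carlo sampling from the posterior;
#' the protected exceedance probability corrects them for the possibility
#' that all models are equally frequent (Bayesian omnibus risk).
#'
#' @param evidence Numeric matrix of log-evidence, participants x models
#'   (column names are model names), e.g. `mean_evidence` from
#'   [crossval_evidence()].
#' @param alpha0 Prior Dirichlet concentration per model (default `1/K`).
#' @param n_samples Monte-Carlo sample size for exceedance probabilities.
#' @param seed Seed for the Monte-Carlo draw.
#' @param max_iter,tol Variational iteration controls.
#' @return Object of class `surnor_bms` with `alpha` (posterior Dirichlet
#'   parameters), `posterior_prob` (expected posterior model
#'   probabilities), `exceedance_prob`, `pxp` (protected exceedance
#'   probabilities), `bor` (Bayesian omnibus risk) and `assignment`
#'   (participant x model responsibility matrix).
#' @export
bms_random_effects <- function(evidence, alpha0 = NULL, n_samples = 1e6,
                               seed = 1L, max_iter = 200L, tol = 1e-8) {
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) stop("log-evidence must be finite")
  n <- nrow(evidence); K <- ncol(evidence)
  if (is.null(alpha0)) alpha0 <- 1 / K
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    alpha_old <- alpha
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw) / rowSums(exp(lw))
    alpha <- a0 + colSums(g)
    if (max(abs(alpha - alpha_old)) < tol) break
  }
  post <- alpha / sum(alpha)
  # Exceedance probabilities by Monte-Carlo over the Dirichlet posterior.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
  xp <- tabulate(max.col(draws, ties.method = "first"), K) / n_samples
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  # Bayesian omnibus risk: posterior probability of the null model in
  # which all participants share equal model frequencies.
  f1 <- rfx_free_energy(evidence, alpha, g, a0)
  f0 <- sum(apply(evidence, 1, function(l) {
    m <- max(l); m + log(mean(exp(l - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / K
  structure(list(alpha = stats::setNames(alpha, colnames(evidence)),
                 posterior_prob = stats::setNames(post, colnames(evidence)),
                 exceedance_prob = stats::setNames(xp, colnames(evidence)),
                 pxp = stats::setNames(pxp, colnames(evidence)),
                 bor = bor, assignment = g),
            class = "surnor_bms")
}

# Negative free energy of the variational random-effects solution.
rfx_free_energy <- function(evidence, alpha, g, a0) {
  elogr <- digamma(alpha) - digamma(sum(alpha))
  expected_ll <- sum(g * evidence)
  expected_prior <- sum(g %*% elogr)
  entropy_g <- -sum(ifelse(g > 0, g * log(g), 0))
  lbeta_fn <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  kl_dir <- lbeta_fn(a0) - lbeta_fn(alpha) + sum((alpha - a0) * elogr)
  expected_ll + expected_prior + entropy_g - kl_dir
}

#' @export
print.surnor_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection (", length(x$alpha),
      "models )\n")
  out <- data.frame(model = names(x$alpha),
                    posterior_prob = round(unname(x$posterior_prob), 4),
                    exceedance = round(unname(x$exceedance_prob), 4),
                    pxp = round(unname(x$pxp), 4))
  print(out, row.names = FALSE)
  cat("Bayesian omnibus risk:", signif(x$bor, 3), "\n")
  invisible(x)
}
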