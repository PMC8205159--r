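# Trial-by-trial encoding analysis of event-related potentials (ERPs)
# against the model variables: decorrelated regressor construction,
# per-timepoint multivariate regression with adjusted R-squared, windowed
# group statistics under FDR control, pooled grand correlations, and a
# synthetic ERP generator that plants a known linear model so the whole
# pipeline is testable without recorded EEG.

ERP_N_TIME <- 65L
ERP_TIMES <- seq(-100, 650, length.out = 65)  # ms relative to state onset

znorm <- function(x, label) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: column '", label, "' has zero variance")
  (x - mean(x)) / s
}

#' Build the decorrelated regressor matrix
#'
#' Normalizes the five model variables; replaces Reward and RPE (which are
#' strongly correlated — both peak at the goal) by their principal
#' components R+ = Reward + RPE and R- = Reward - RPE (renormalized); and
#' orthogonalizes Surprise, Novelty and NPE to the span of R+ and R-,
#' renormalizing afterwards. The orthogonalized columns remain highly
#' correlated with their raw sources on realistic data.
#'
#' @param vars Data frame with columns `surprise`, `novelty`, `npe`,
#'   `rpe`, `reward` (from [model_variables()]); at least 6 rows.
#' @return Numeric matrix with columns `surprise_perp`, `novelty_perp`,
#'   `npe_perp`, `r_plus`, `r_minus`, all zero-mean unit-variance; the raw
#'   normalized matrix is kept in `attr(, "raw")`.
#' @export
build_regressors <- function(vars) {
  need <- c("surprise", "novelty", "npe", "rpe", "reward")
  stopifnot(all(need %in% names(vars)))
  if (nrow(vars) < 6L) stop("at least 6 trials are required")
  raw <- sapply(need, function(nm) znorm(vars[[nm]], nm))
  r_plus <- raw[, "reward"] + raw[, "rpe"]
  r_minus <- raw[, "reward"] - raw[, "rpe"]
  if (stats::sd(r_minus) < 1e-10)
    stop("degenerate input: Reward and RPE are perfectly correlated; R- is degenerate")
  if (stats::sd(r_plus) < 1e-10)
    stop("degenerate input: Reward and RPE are perfectly anti-correlated; R+ is degenerate")
  r_plus <- znorm(r_plus, "r_plus")
  r_minus <- znorm(r_minus, "r_minus")
  basis <- cbind(r_plus, r_minus)
  perp <- sapply(c("surprise", "novelty", "npe"), function(nm) {
    x <- raw[, nm]
    res <- stats::lm.fit(cbind(1, basis), x)$residuals
    znorm(res, paste0(nm, "_perp"))
  })
  X <- cbind(perp, r_plus = r_plus, r_minus = r_minus)
  colnames(X) <- c("surprise_perp", "novelty_perp", "npe_perp",
                   "r_plus", "r_minus")
  attr(X, "raw") <- raw
  X
}

#' Per-timepoint multivariate linear regression of ERPs
#'
#' Ordinary least squares of the normalized ERP amplitude at each time
#' point on the five regressors, returning coefficients and the adjusted
#' R-squared encoding power (which can be negative under the null).
#'
#' @param X Regressor matrix from [build_regressors()].
#' @param Y ERP matrix, trials x time points (same trials as `X`).
#' @return List with `coefficients` (regressors x time points),
#'   `adj_r_squared` (per time point) and `times` (ms).
#' @export
encode_mlr <- function(X, Y) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of trials")
  if (n < p + 2L) stop("need at least ", p + 2L, " trials for ", p, " regressors")
  if (qr(X)$rank < p)
    stop("rank-deficient design; rebuild the regressors (build_regressors)")
  nt <- ncol(Y)
  Yn <- apply(Y, 2, function(y) {
    s <- stats::sd(y)
    if (s == 0) rep(0, n) else (y - mean(y)) / s
  })
  D <- cbind(1, X)
  fit <- stats::lm.fit(D, Yn)
  beta <- fit$coefficients[-1, , drop = FALSE]
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  tss <- colSums(sweep(Yn, 2, colMeans(Yn))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  rownames(beta) <- colnames(X)
  times <- if (nt == ERP_N_TIME) ERP_TIMES else seq_len(nt)
  list(coefficients = beta, adj_r_squared = adj, times = times)
}

group_windows <- function(idx) {
  if (length(idx) == 0L) return(list())
  br <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(br) - 1L), function(k) idx[(br[k] + 1L):br[k + 1L]])
}

#' Group-level window statistics of encoding power
#'
#' One-sample t-tests of the per-participant encoding power against zero
#' at each post-baseline time point, Benjamini-Hochberg FDR control at
#' `alpha_fdr`; contiguous significant points form windows, and windows
#' longer than `split_span` points are split into two equal halves. Within
#' each window the time-averaged regression coefficients are t-tested
#' across participants with FDR control per window.
#'
#' @param fits List of per-participant results from [encode_mlr()] (at
#'   least 2).
#' @param alpha_fdr FDR level (default 0.1).
#' @param split_span Maximum window length (time points) before splitting
#'   (default 8).
#' @param baseline_ms Time points at or after this value (ms) enter the
#'   tests (default 0: post-onset only).
#' @return List with `power` (data frame per time point: mean, se, p,
#'   p_fdr, significant), `windows` (list of index vectors) and
#'   `window_coefficients` (data frame per window x regressor: mean, se,
#'   p, p_fdr, significant).
#' @export
window_stats <- function(fits, alpha_fdr = 0.1, split_span = 8L,
                         baseline_ms = 0) {
  if (length(fits) < 2L) stop("at least 2 participants are required")
  pow <- do.call(rbind, lapply(fits, `[[`, "adj_r_squared"))
  times <- fits[[1]]$times
  nt <- ncol(pow)
  post <- which(times >= baseline_ms)
  pvals <- rep(NA_real_, nt)
  for (j in post) pvals[j] <- stats::t.test(pow[, j], alternative = "greater")$p.value
  p_fdr <- rep(NA_real_, nt)
  p_fdr[post] <- stats::p.adjust(pvals[post], method = "BH")
  sig <- which(!is.na(p_fdr) & p_fdr <= alpha_fdr)
  wins <- group_windows(sig)
  wins <- do.call(c, lapply(wins, function(w) {
    if (length(w) > split_span) {
      h <- length(w) %/% 2L
      list(w[seq_len(h)], w[(h + 1L):length(w)])
    } else list(w)
  }))
  if (is.null(wins)) wins <- list()
  wc <- NULL
  if (length(wins)) {
    wc <- do.call(rbind, lapply(seq_along(wins), function(k) {
      w <- wins[[k]]
      # participant x regressor matrix of time-averaged coefficients
      bmat <- t(vapply(fits, function(f)
        rowMeans(f$coefficients[, w, drop = FALSE]), numeric(nrow(fits[[1]]$coefficients))))
      pv <- apply(bmat, 2, function(b) stats::t.test(b)$p.value)
      pf <- stats::p.adjust(pv, method = "BH")
      data.frame(window = k, regressor = colnames(bmat),
                 t_start = times[min(w)], t_end = times[max(w)],
                 mean = colMeans(bmat),
                 se = apply(bmat, 2, stats::sd) / sqrt(nrow(bmat)),
                 p = pv, p_fdr = pf, significant = pf <= alpha_fdr,
                 row.names = NULL)
    }))
  }
  list(power = data.frame(time = times,
                          mean = colMeans(pow),
                          se = apply(pow, 2, stats::sd) / sqrt(nrow(pow)),
                          p = pvals, p_fdr = p_fdr,
                          significant = seq_len(nt) %in% sig),
       windows = wins, window_coefficients = wc)
}

#' Pooled grand correlation of model variables with the ERP
#'
#' Normalizes each participant's ERP matrix by its overall squared energy
#' (the mean of squared amplitudes over all trials and time points), pools
#' all trials, and correlates each raw model variable with the pooled
#' amplitude per time point, with Fisher-z 95% confidence intervals and
#' BH-FDR control at `alpha_fdr` over post-onset points. For RPE, trials
#' of the first episode of the first block are excluded.
#'
#' @param vars_list Per-participant model-variable data frames (with
#'   `block`, `episode` context columns).
#' @param erp_list Per-participant ERP matrices (trials x time points).
#' @param alpha_fdr FDR level (default 0.1).
#' @param baseline_ms Post-onset cutoff for the FDR family.
#' @return Data frame per (variable, time point): correlation, CI bounds,
#'   p, p_fdr, significant.
#' @export
grand_correlation <- function(vars_list, erp_list, alpha_fdr = 0.1,
                              baseline_ms = 0) {
  stopifnot(length(vars_list) == length(erp_list), length(vars_list) >= 2L)
  Yp <- lapply(erp_list, function(Y) {
    Y <- as.matrix(Y)
    en <- mean(Y^2)
    if (en == 0) stop("all-zero ERP matrix")
    # divide by the RMS amplitude so every participant contributes with
    # unit second moment (scale-invariant by construction)
    Y / sqrt(en)
  })
  Y <- do.call(rbind, Yp)
  Vs <- do.call(rbind, vars_list)
  times <- if (ncol(Y) == ERP_N_TIME) ERP_TIMES else seq_len(ncol(Y))
  post <- which(times >= baseline_ms)
  varnames <- c("surprise", "novelty", "npe", "rpe", "reward")
  out <- list()
  for (nm in varnames) {
    keep <- if (nm == "rpe") !(Vs$block == 1L & Vs$episode == 1L)
            else rep(TRUE, nrow(Vs))
    if (!any(keep)) stop("no trials left for '", nm, "' after exclusions")
    x <- Vs[[nm]][keep]
    if (stats::sd(x) == 0) stop("degenerate input: variable '", nm, "' is constant")
    n <- sum(keep)
    r <- as.numeric(stats::cor(x, Y[keep, , drop = FALSE]))
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    zse <- 1 / sqrt(n - 3)
    pv <- 2 * stats::pnorm(-abs(z) / zse)
    pf <- rep(NA_real_, length(r))
    pf[post] <- stats::p.adjust(pv[post], method = "BH")
    out[[nm]] <- data.frame(
      variable = nm, time = times, r = r,
      ci_lo = tanh(z - 1.96 * zse), ci_hi = tanh(z + 1.96 * zse),
      p = pv, p_fdr = pf,
      significant = !is.na(pf) & pf <= alpha_fdr, n = n)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate synthetic ERP matrices from a planted linear model
#'
#' `Y = X %*% b_profile + noise`, with independent Gaussian noise, giving a
#' ground-truth dataset for the regression pipeline.
#'
#' @param X Regressor matrix (trials x regressors).
#' @param b_profile Coefficient-by-time matrix (regressors x 65).
#' @param noise_sd Noise standard deviation.
#' @param seed Seed.
#' @return Trials x 65 ERP matrix.
#' @export
synth_erp <- function(X, b_profile, noise_sd = 1, seed = 1L) {
  X <- as.matrix(X); b_profile <- as.matrix(b_profile)
  if (ncol(X) != nrow(b_profile))
    stop("shape mismatch: ncol(X) must equal nrow(b_profile)")
  if (ncol(b_profile) != ERP_N_TIME)
    stop("b_profile must have ", ERP_N_TIME, " time columns")
  set.seed(as.integer(seed))
  X %*% b_profile + matrix(stats::rnorm(nrow(X) * ERP_N_TIME, sd = noise_sd),
                           nrow(X), ERP_N_TIME)
}

#' A coefficient-by-time profile with a positive peak near 300 ms
#'
#' Convenience default for planting signal in [synth_erp()]: Gaussian bumps
#' centred at `peak_ms` for the selected regressors, zero elsewhere.
#'
#' @param regressors Character names matching [build_regressors()] columns.
#' @param active Which regressors carry signal.
#' @param amplitude Peak coefficient value.
#' @param peak_ms,width_ms Peak location and width (ms).
#' @return Regressors x 65 matrix.
#' @export
erp_peak_profile <- function(regressors = c("surprise_perp", "novelty_perp",
                                            "npe_perp", "r_plus", "r_minus"),
                             active = c("surprise_perp", "novelty_perp",
                                        "npe_perp", "r_plus"),
                             amplitude = 1, peak_ms = 300, width_ms = 40) {
  b <- matrix(0, length(regressors), ERP_N_TIME,
              dimnames = list(regressors, NULL))
  bump <- amplitude * exp(-0.5 * ((ERP_TIMES - peak_ms) / width_ms)^2)
  for (nm in intersect(active, regressors)) b[nm, ] <- bump
  b
}
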