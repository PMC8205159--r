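# Model roster and parameter handling. The full agent has 18 free
# parameters in four groups: world-model (epsilon, m, t_ps), softmax /
# exploration-exploitation (beta_1, beta_2, beta_n1, beta_n2),
# discount/trace (lambda_r, lambda_n, mu_r, mu_n), model-free (rho_b,
# delta_rho, q_n0) and model-based/model-free trade-off (omega_0, omega_11,
# omega_12, omega_scale). Reduced models expose subsets; variant-specific
# extras (optimistic initial value, leak constant, binary-novelty
# threshold) are free parameters of those variants only.

PARAM_NAMES <- c("epsilon", "m", "t_ps",
                 "beta_1", "beta_2", "beta_n1", "beta_n2",
                 "lambda_r", "lambda_n", "mu_r", "mu_n",
                 "rho_b", "delta_rho", "q_n0",
                 "omega_0", "omega_11", "omega_12", "omega_scale",
                 "gamma_leak", "q_oi", "bn_theta", "bn_n")

#' Agent parameter set
#'
#' Returns the package's default parameter set, optionally overridden.
#' The defaults were calibrated once so that simulated full-model cohorts
#' reproduce the published behavioral profile of the fitted model: a
#' baseline model-free learning rate of 0.06 with a surprise-saturated rate
#' more than 8 times larger, episode-1 lengths of order one hundred actions
#' in block 1 and shorter in block 2, and roughly a third of 200 simulated
#' agents exceeding 500 actions in some episode.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named numeric vector of class `surnor_params`.
#' @examples
#' p <- surnor_params(rho_b = 0.05)
#' p["rho_b"]
#' @export
surnor_params <- function(...) {
  p <- c(
    epsilon = 0.01, m = 0.2, t_ps = 30,
    beta_1 = 25, beta_2 = 60, beta_n1 = 0.003, beta_n2 = 0.01,
    lambda_r = 0.95, lambda_n = 0.9, mu_r = 0.8, mu_n = 0.8,
    rho_b = 0.06, delta_rho = 0.5, q_n0 = 24,
    omega_0 = 0.8, omega_11 = 0.75, omega_12 = 0.25, omega_scale = 1,
    gamma_leak = 0.02, q_oi = 0.5, bn_theta = 10, bn_n = 3)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), PARAM_NAMES)
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_params(p)
  structure(p, class = "surnor_params")
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stop("invalid parameters: ", msg)
  chk(p[["epsilon"]] > 0, "epsilon must be positive")
  chk(p[["m"]] >= 0, "m must be non-negative")
  chk(p[["t_ps"]] >= 0, "t_ps must be non-negative")
  for (nm in c("lambda_r", "lambda_n", "mu_r", "mu_n", "omega_0",
               "omega_11", "omega_12", "gamma_leak"))
    chk(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must be in [0, 1]"))
  chk(p[["lambda_r"]] < 1, "lambda_r must be < 1 for the Bellman solve")
  chk(p[["lambda_n"]] < 1, "lambda_n must be < 1 for the Bellman solve")
  chk(p[["rho_b"]] >= 0, "rho_b must be non-negative")
  chk(p[["delta_rho"]] >= 0, "delta_rho must be non-negative")
  invisible(p)
}

#' The model roster
#'
#' The shipped roster: the full surprise-novelty-reward model (`SurNoR`),
#' the random-choice null (`RC`), 11 alternatives crossing policy
#' (model-based `MB`, model-free `MF`, hybrid `Hyb`) with exploration
#' strategy (novelty-seeking `+N`, optimistic initialization `+OI`,
#' uncertainty/surprisal-seeking `+U`) and surprise-modulated learning
#' (`+S`), plus two Binary-Novelty controls that replace the graded novelty
#' signal by a fixed negative reward for over-visited states.
#'
#' @param include_controls Include the two Binary-Novelty controls
#'   (default `TRUE`).
#' @return Data frame with columns `name`, `policy`, `exploration`,
#'   `surprise_mod`, `binary_novelty`, `n_free_params`.
#' @export
model_roster <- function(include_controls = TRUE) {
  ro <- rbind(
    data.frame(name = "SurNoR",    policy = "Hyb", exploration = "novelty", surprise_mod = TRUE),
    data.frame(name = "MB+S+OI",   policy = "MB",  exploration = "optimistic_init", surprise_mod = TRUE),
    data.frame(name = "MB+S+U",    policy = "MB",  exploration = "uncertainty", surprise_mod = TRUE),
    data.frame(name = "MB+N",      policy = "MB",  exploration = "novelty", surprise_mod = FALSE),
    data.frame(name = "MB+S+N",    policy = "MB",  exploration = "novelty", surprise_mod = TRUE),
    data.frame(name = "MF+OI",     policy = "MF",  exploration = "optimistic_init", surprise_mod = FALSE),
    data.frame(name = "MF+S+U",    policy = "MF",  exploration = "uncertainty", surprise_mod = TRUE),
    data.frame(name = "MF+N",      policy = "MF",  exploration = "novelty", surprise_mod = FALSE),
    data.frame(name = "MF+S+N",    policy = "MF",  exploration = "novelty", surprise_mod = TRUE),
    data.frame(name = "Hyb+S+OI",  policy = "Hyb", exploration = "optimistic_init", surprise_mod = TRUE),
    data.frame(name = "Hyb+S+U",   policy = "Hyb", exploration = "uncertainty", surprise_mod = TRUE),
    data.frame(name = "Hyb+N",     policy = "Hyb", exploration = "novelty", surprise_mod = FALSE),
    data.frame(name = "RC",        policy = "RC",  exploration = "none", surprise_mod = FALSE))
  ro$binary_novelty <- "off"
  if (include_controls) {
    bn <- data.frame(
      name = c("SurNoR-BN-threshold", "SurNoR-BN-topn"),
      policy = "Hyb", exploration = "binary_novelty", surprise_mod = TRUE,
      binary_novelty = c("threshold", "top_n"))
    ro <- rbind(ro, bn)
  }
  ro$n_free_params <- vapply(seq_len(nrow(ro)), function(i)
    length(free_parameters(model_spec(ro$name[i], roster = ro))), integer(1))
  ro
}

model_spec <- function(name, roster = NULL) {
  if (is.null(roster)) roster <- model_roster()
  i <- match(name, roster$name)
  if (is.na(i)) stop("unknown model '", name, "'; roster: ",
                     paste(roster$name, collapse = ", "))
  as.list(roster[i, c("name", "policy", "exploration", "surprise_mod",
                      "binary_novelty")])
}

#' Free parameters of a model
#'
#' Which of the parameter vector's entries actually influence the model's
#' behavior. The full model has 18; the Binary-Novelty controls 19 (the
#' magnitude of their fixed negative reward is absorbed by the novelty
#' weights, leaving one extra threshold parameter); the random-choice null
#' has none.
#'
#' @param spec A model name or the result of an internal model lookup.
#' @return Character vector of free-parameter names.
#' @export
free_parameters <- function(spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$policy == "RC") return(character(0))
  uses_mb <- spec$policy %in% c("MB", "Hyb")
  uses_mf <- spec$policy %in% c("MF", "Hyb")
  nov_channel <- spec$exploration %in% c("novelty", "uncertainty", "binary_novelty")
  uses_wm <- uses_mb || spec$surprise_mod || spec$exploration == "uncertainty"
  free <- c("beta_1", "beta_2", "lambda_r")
  if (uses_wm) free <- c(free, "epsilon")
  if (spec$surprise_mod) free <- c(free, "m") else if (uses_wm) free <- c(free, "gamma_leak")
  if (uses_mb) free <- c(free, "t_ps")
  if (nov_channel) free <- c(free, "beta_n1", "beta_n2", "lambda_n")
  if (uses_mf) {
    free <- c(free, "mu_r", "rho_b")
    if (spec$surprise_mod) free <- c(free, "delta_rho")
    if (nov_channel) free <- c(free, "mu_n", "q_n0")
  }
  if (spec$policy == "Hyb") {
    free <- c(free, "omega_0", "omega_scale")
    if (nov_channel) free <- c(free, "omega_11", "omega_12")
  }
  if (spec$exploration == "optimistic_init") free <- c(free, "q_oi")
  if (spec$binary_novelty == "threshold") free <- c(free, "bn_theta")
  if (spec$binary_novelty == "top_n") free <- c(free, "bn_n")
  intersect(PARAM_NAMES, free)
}

# Integer codes shared with the C++ core.
spec_flags <- function(spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  list(policy = match(spec$policy, c("RC", "MB", "MF", "Hyb")) - 1L,
       exploration = match(spec$exploration,
                           c("none", "novelty", "optimistic_init",
                             "uncertainty", "binary_novelty")) - 1L,
       surprise_mod = as.integer(isTRUE(spec$surprise_mod)),
       binary_novelty = match(spec$binary_novelty,
                              c("off", "threshold", "top_n")) - 1L,
       count_goal = 1L)
}
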