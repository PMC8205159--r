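# Task environment: 10 non-goal states (progressing 1-7, traps 8-10) plus an
# absorbing goal state G (coded 11), 4 actions per non-goal state, and an
# unannounced swap of the images of states 3 and 7 between blocks 1 and 2.

GOAL_STATE <- 11L
N_STATES <- 11L
N_ACTIONS <- 4L
PROGRESSING <- 1:7
TRAPS <- 8:10
SWAP_PAIR <- c(3L, 7L)

#' Construct the two-block task environment
#'
#' Builds the deterministic 11-state, 4-action environment: at each
#' progressing state (1-7) one `good` action moves one step closer to the
#' goal (state 7's good action reaches G), one `neutral` action stays, and
#' two `bad` actions fall into the trap set (8-10); each trap state has one
#' `escape` action to state 1 and three `trap_internal` actions within the
#' trap set. The swap pair (3, 7) always shares at least one action label
#' with a common trap successor, so that one action from each swapped state
#' leads to the same trap state both before and after the swap.
#'
#' @param seed Integer seed controlling the random assignment of action
#'   labels to roles (the underlying role structure is fixed).
#' @param canonical If `TRUE` (default) return the single fixed environment
#'   used throughout the package's analyses, ignoring `seed`. Its action
#'   labels match the published figures: the neutral action is action 2 in
#'   state 1 and action 3 in state 3; the good action is action 1 in state 7
#'   and action 4 in state 3.
#' @return An object of class `surnor_env`: a list with `trans` (10 x 4
#'   integer matrix of successor states), `roles` (10 x 4 character matrix),
#'   `goal`, `swap_pair`, `n_states`, `n_actions` and `seed`.
#' @examples
#' env <- build_environment()
#' env$trans[7, ]  # action 1 reaches the goal (11)
#' @export
build_environment <- function(seed = 1L, canonical = TRUE) {
  if (canonical) {
    trans <- matrix(NA_integer_, 10, 4)
    trans[1, ] <- c(2L, 1L, 8L, 9L)
    trans[2, ] <- c(2L, 10L, 3L, 8L)
    trans[3, ] <- c(8L, 9L, 3L, 4L)
    trans[4, ] <- c(10L, 5L, 9L, 4L)
    trans[5, ] <- c(6L, 8L, 5L, 10L)
    trans[6, ] <- c(9L, 6L, 10L, 7L)
    trans[7, ] <- c(11L, 9L, 7L, 8L)
    trans[8, ] <- c(8L, 9L, 1L, 10L)
    trans[9, ] <- c(1L, 10L, 9L, 8L)
    trans[10, ] <- c(9L, 8L, 10L, 1L)
    return(new_surnor_env(trans, seed = NA_integer_))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Seeded label assignment: roles per state are fixed, labels permuted.
  gen <- function(seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    trans <- matrix(NA_integer_, 10, 4)
    # Shared swap-invariant trap action: same label, same trap successor at
    # both swapped states.
    a_shared <- sample.int(4L, 1L)
    trap_shared <- sample(TRAPS, 1L)
    for (s in PROGRESSING) {
      succ_good <- if (s == 7L) GOAL_STATE else s + 1L
      bad_traps <- sample(TRAPS, 2L, replace = TRUE)
      if (s %in% SWAP_PAIR) {
        labs <- sample(setdiff(1:4, a_shared))
        trans[s, a_shared] <- trap_shared
        trans[s, labs[1]] <- succ_good
        trans[s, labs[2]] <- s
        trans[s, labs[3]] <- bad_traps[1]
      } else {
        labs <- sample.int(4L)
        trans[s, labs[1]] <- succ_good
        trans[s, labs[2]] <- s
        trans[s, labs[3]] <- bad_traps[1]
        trans[s, labs[4]] <- bad_traps[2]
      }
    }
    for (s in TRAPS) {
      labs <- sample.int(4L)
      trans[s, labs[1]] <- 1L
      trans[s, labs[2:4]] <- sample(TRAPS, 3L, replace = TRUE)
    }
    trans
  }
  new_surnor_env(gen(seed), seed = as.integer(seed))
}

new_surnor_env <- function(trans, seed) {
  roles <- role_table(trans)
  env <- structure(
    list(trans = trans, roles = roles, goal = GOAL_STATE,
         swap_pair = SWAP_PAIR, n_states = N_STATES, n_actions = N_ACTIONS,
         seed = seed),
    class = "surnor_env")
  validate_environment(env)
  env
}

role_table <- function(trans) {
  roles <- matrix(NA_character_, 10, 4)
  for (s in PROGRESSING) {
    succ_good <- if (s == 7L) GOAL_STATE else s + 1L
    for (a in 1:4) {
      roles[s, a] <-
        if (trans[s, a] == succ_good) "good"
        else if (trans[s, a] == s) "neutral"
        else if (trans[s, a] %in% TRAPS) "bad"
        else NA_character_
    }
  }
  for (s in TRAPS) {
    for (a in 1:4) {
      roles[s, a] <-
        if (trans[s, a] == 1L) "escape"
        else if (trans[s, a] %in% TRAPS) "trap_internal"
        else NA_character_
    }
  }
  roles
}

validate_environment <- function(env) {
  trans <- env$trans
  roles <- env$roles
  if (any(is.na(trans)) || any(trans < 1L) || any(trans > N_STATES))
    stop("environment invariant violated: transitions must be total over non-goal states")
  if (any(is.na(roles)))
    stop("environment invariant violated: every action must have a defined role")
  for (s in PROGRESSING) {
    cnt <- table(factor(roles[s, ], levels = c("good", "neutral", "bad")))
    if (cnt[["good"]] != 1L || cnt[["neutral"]] != 1L || cnt[["bad"]] != 2L)
      stop(sprintf("environment invariant violated: progressing state %d must have 1 good, 1 neutral, 2 bad actions", s))
  }
  for (s in TRAPS) {
    cnt <- table(factor(roles[s, ], levels = c("escape", "trap_internal")))
    if (cnt[["escape"]] != 1L || cnt[["trap_internal"]] != 3L)
      stop(sprintf("environment invariant violated: trap state %d must have 1 escape and 3 trap-internal actions", s))
  }
  shared <- which(trans[env$swap_pair[1], ] == trans[env$swap_pair[2], ] &
                    trans[env$swap_pair[1], ] %in% TRAPS)
  if (length(shared) == 0L)
    stop("environment invariant violated: cannot place the swap-invariant trap action (no action label leads to the same trap state from both swapped states)")
  invisible(env)
}

#' @export
print.surnor_env <- function(x, ...) {
  cat("Two-block goal-search environment:", x$n_states, "states (goal =",
      x$goal, "),", x$n_actions, "actions\n")
  cat("Swap pair (block 2):", x$swap_pair[1], "<->", x$swap_pair[2], "\n")
  cat("Transition table (rows = states, cols = actions):\n")
  print(x$trans)
  invisible(x)
}

#' Observation map implementing the block-2 state swap
#'
#' Returns the permutation of displayed state labels in effect after the
#' unannounced swap: the transposition of the swap pair (3, 7), identity on
#' every other state. Applying it twice is the identity.
#'
#' @param env A `surnor_env`.
#' @return Integer vector of length 11 mapping displayed labels to
#'   underlying labels (an involution).
#' @export
apply_swap <- function(env) {
  stopifnot(inherits(env, "surnor_env"))
  perm <- seq_len(env$n_states)
  perm[env$swap_pair[1]] <- env$swap_pair[2]
  perm[env$swap_pair[2]] <- env$swap_pair[1]
  perm
}

identity_map <- function(env) seq_len(env$n_states)

#' Execute one environment transition
#'
#' Un-permutes the displayed state through the observation map, applies the
#' underlying deterministic transition, and re-permutes the successor.
#' Reward is 1 iff the successor is the goal.
#'
#' @param env A `surnor_env`.
#' @param obs_map Observation permutation (from [apply_swap()] in block 2,
#'   or `NULL`/identity in block 1).
#' @param state Displayed (observed) non-goal state label.
#' @param action Action label 1-4.
#' @return List with `next_state` (displayed label) and `reward` (0/1).
#' @export
env_step <- function(env, obs_map = NULL, state, action) {
  stopifnot(inherits(env, "surnor_env"))
  if (is.null(obs_map)) obs_map <- identity_map(env)
  if (state == env$goal) stop("cannot step from the goal state (episodes end there)")
  stopifnot(state >= 1L, state <= 10L, action >= 1L, action <= 4L)
  u <- obs_map[state]
  u_next <- env$trans[u, action]
  list(next_state = obs_map[u_next], reward = as.integer(u_next == env$goal))
}

#' Displayed transition table for a block
#'
#' @param env A `surnor_env`.
#' @param block Block number (1 or 2); block 2 applies the swap.
#' @return 10 x 4 integer matrix of displayed successors.
#' @export
displayed_transitions <- function(env, block = 1L) {
  stopifnot(block %in% c(1L, 2L))
  if (block == 1L) return(env$trans)
  perm <- apply_swap(env)
  dt <- matrix(NA_integer_, 10, 4)
  for (s in 1:10) dt[s, ] <- perm[env$trans[perm[s], ]]
  dt
}

#' Expected hitting time of the goal under the uniform random policy
#'
#' Solves the linear first-passage system for the Markov chain induced by
#' choosing each action with probability 1/4, giving the exact expected
#' number of actions to reach the goal from every non-goal state. A
#' Monte-Carlo estimator is available for cross-checking.
#'
#' @param env A `surnor_env`.
#' @param method `"analytic"` (default, exact linear solve) or
#'   `"monte_carlo"`.
#' @param n_episodes Number of simulated episodes per start state for the
#'   Monte-Carlo method.
#' @param seed Seed for the Monte-Carlo method.
#' @return List with `per_state` (named vector of expectations for states
#'   1-10), `mean` (average over the 10 non-goal start states), and for the
#'   Monte-Carlo method `se` (standard errors per state).
#' @export
expected_hitting_time <- function(env, method = c("analytic", "monte_carlo"),
                                  n_episodes = 10000L, seed = 1L) {
  stopifnot(inherits(env, "surnor_env"))
  method <- match.arg(method)
  if (method == "analytic") {
    P <- matrix(0, 10, N_STATES)
    for (s in 1:10) for (a in 1:4)
      P[s, env$trans[s, a]] <- P[s, env$trans[s, a]] + 0.25
    A <- diag(10) - P[, 1:10, drop = FALSE]
    h <- tryCatch(solve(A, rep(1, 10)),
                  error = function(e) stop("goal unreachable under the uniform policy: first-passage system is singular"))
    names(h) <- as.character(1:10)
    return(list(per_state = h, mean = mean(h)))
  }
  set.seed(as.integer(seed))
  res <- cpp_hitting_mc(env$trans, as.integer(n_episodes))
  h <- res$mean
  names(h) <- as.character(1:10)
  se <- res$se
  names(se) <- as.character(1:10)
  list(per_state = h, mean = mean(h), se = se)
}

#' Shortest action path length between displayed states
#'
#' Breadth-first search on the displayed transition table.
#'
#' @param env A `surnor_env`.
#' @param from,to Displayed state labels.
#' @param block Block (1 or 2).
#' @return Integer path length in actions (`Inf` if unreachable).
#' @export
shortest_path_length <- function(env, from, to, block = 1L) {
  dt <- displayed_transitions(env, block)
  dist <- rep(Inf, N_STATES)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    if (s == to) return(dist[s])
    if (s == GOAL_STATE) next
    for (a in 1:4) {
      nx <- dt[s, a]
      if (dist[nx] > dist[s] + 1) {
        dist[nx] <- dist[s] + 1
        queue <- c(queue, nx)
      }
    }
  }
  dist[to]
}

#' Serialize / restore an environment as JSON
#'
#' @param env A `surnor_env`.
#' @param path File path.
#' @return `read_environment` returns a `surnor_env`.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "surnor_env"))
  obj <- list(trans = unclass(env$trans), roles = unclass(env$roles),
              goal = env$goal, swap_pair = env$swap_pair, seed = env$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- suppressWarnings(as.integer(obj$seed[1]))
  if (length(seed) == 0L) seed <- NA_integer_
  new_surnor_env(matrix(as.integer(obj$trans), 10, 4), seed = seed)
}
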