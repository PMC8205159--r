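# Behavioral summaries: episode lengths, trap-escape latencies and
# progress scores, computed identically for simulated or externally
# supplied trajectory tables.

#' Moving average of length three
#'
#' Centered window, shrunk at the boundaries (length-2 at the ends).
#'
#' @param x Numeric vector.
#' @param width Window width (default 3).
#' @export
moving_average <- function(x, width = 3L) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
}

#' Episode lengths
#'
#' Number of actions per episode per participant, with cohort means and
#' standard errors. Truncated episodes (those not ending at the goal) are
#' flagged and excluded from the cohort summary by default.
#'
#' @param cohort List of trajectory data frames (or a single one).
#' @param goal Goal state label.
#' @param drop_truncated Exclude truncated episodes from the summary.
#' @return List with `per_episode` (data frame: participant, block,
#'   episode, n_actions, truncated) and `summary` (block, episode, mean,
#'   se, n).
#' @export
episode_lengths <- function(cohort, goal = 11L, drop_truncated = TRUE) {
  if (is.data.frame(cohort)) cohort <- list(cohort)
  per <- do.call(rbind, lapply(cohort, function(tr) {
    sp <- split(tr, list(tr$block, tr$episode), drop = TRUE)
    do.call(rbind, lapply(sp, function(e) {
      data.frame(participant = e$participant[1], block = e$block[1],
                 episode = e$episode[1], n_actions = nrow(e),
                 truncated = e$next_state[nrow(e)] != goal)
    }))
  }))
  rownames(per) <- NULL
  per <- per[order(per$participant, per$block, per$episode), ]
  use <- if (drop_truncated) !per$truncated else rep(TRUE, nrow(per))
  agg <- aggregate(n_actions ~ block + episode, data = per[use, ],
                   FUN = function(v) c(mean = mean(v),
                                       se = stats::sd(v) / sqrt(length(v)),
                                       n = length(v)))
  summary <- data.frame(block = agg$block, episode = agg$episode,
                        mean = agg$n_actions[, "mean"],
                        se = agg$n_actions[, "se"], n = agg$n_actions[, "n"])
  list(per_episode = per, summary = summary)
}

# Per-participant trap-escape latencies in one episode: number of actions
# from falling into the trap set until first reaching `target` (state 2).
escape_latencies_one <- function(tr, block, episode, traps = 8:10,
                                 target = 2L) {
  e <- tr[tr$block == block & tr$episode == episode, ]
  lat <- integer(0)
  i <- 1L
  n <- nrow(e)
  while (i <= n) {
    entering <- e$state[i] %in% traps &&
      (i == 1L || !(e$state[i - 1L] %in% traps))
    if (entering) {
      j <- i
      while (j <= n && e$next_state[j] != target) j <- j + 1L
      if (j <= n) lat <- c(lat, j - i + 1L) # escape completed within episode
      i <- j + 1L
    } else i <- i + 1L
  }
  lat
}

#' Trap-escape latency curves
#'
#' For each participant, the number of actions between falling into a trap
#' state and first reaching state 2, indexed by the participant's trap
#' visit number; cohort medians with 25/75% quantiles per visit index,
#' smoothed with a moving average of length three. The minimum possible
#' latency is 2 (trap -> state 1 -> state 2).
#'
#' @param cohort List of trajectory data frames.
#' @param block,episode Which episode to analyse (default episode 1).
#' @param traps Trap state labels.
#' @param target Escape target (state 2).
#' @return Data frame: visit index, median, q25, q75, n (cohort size at
#'   that index), all latency summaries moving-average smoothed.
#' @export
escape_latency <- function(cohort, block = 1L, episode = 1L, traps = 8:10,
                           target = 2L) {
  if (is.data.frame(cohort)) cohort <- list(cohort)
  lats <- lapply(cohort, escape_latencies_one, block = block,
                 episode = episode, traps = traps, target = target)
  max_v <- max(c(0L, vapply(lats, length, integer(1))))
  if (max_v == 0L)
    return(data.frame(visit = integer(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0), n = integer(0)))
  stats_v <- t(vapply(seq_len(max_v), function(v) {
    vals <- unlist(lapply(lats, function(l) if (length(l) >= v) l[v] else NULL))
    c(stats::median(vals), stats::quantile(vals, 0.25),
      stats::quantile(vals, 0.75), length(vals))
  }, numeric(4)))
  data.frame(visit = seq_len(max_v),
             median = moving_average(stats_v[, 1]),
             q25 = moving_average(stats_v[, 2]),
             q75 = moving_average(stats_v[, 3]),
             n = as.integer(stats_v[, 4]))
}

PROGRESS_VALUES <- c(good = 1, neutral = 0.5, bad = -0.75)

#' Progress score at progressing states
#'
#' Assigns +1 to good actions, +0.5 to neutral actions and -0.75 to bad
#' actions (so the expectation under uniform random choice is zero), maps
#' every visit of the given displayed states to its value via the
#' environment's role table, and averages across participants per visit
#' index (moving average of length three). In block 2 the roles of
#' displayed states are those of the underlying states after the swap, so
#' scores at swapped states are computed against the swapped roles.
#'
#' @param cohort List of trajectory data frames.
#' @param env A `surnor_env`.
#' @param states Displayed progressing states to score.
#' @param block,episode Which episode to analyse.
#' @return Data frame: state, visit, mean, se, n.
#' @export
progress_score <- function(cohort, env, states = c(1L, 2L, 3L, 4L),
                           block = 1L, episode = 1L) {
  if (is.data.frame(cohort)) cohort <- list(cohort)
  perm <- if (block == 2L) apply_swap(env) else identity_map(env)
  out <- list()
  for (st in states) {
    u <- perm[st]
    if (!(u %in% 1:7)) stop("progress is defined at progressing states; state ",
                            st, " maps to ", u)
    vals <- lapply(cohort, function(tr) {
      e <- tr[tr$block == block & tr$episode == episode & tr$state == st, ]
      if (nrow(e) == 0L) return(numeric(0))
      roles <- env$roles[u, e$action]
      if (any(is.na(roles))) stop("undefined action role at state ", st)
      unname(PROGRESS_VALUES[roles])
    })
    max_v <- max(c(0L, vapply(vals, length, integer(1))))
    if (max_v == 0L) next
    sm <- t(vapply(seq_len(max_v), function(v) {
      x <- unlist(lapply(vals, function(l) if (length(l) >= v) l[v] else NULL))
      c(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
    }, numeric(3)))
    out[[as.character(st)]] <- data.frame(
      state = st, visit = seq_len(max_v),
      mean = moving_average(sm[, 1]), se = sm[, 2], n = as.integer(sm[, 3]))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
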