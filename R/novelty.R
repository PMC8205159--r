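# Count-based novelty: a state's novelty is the negative log of its
# Laplace-smoothed observation frequency. Counts accumulate over the whole
# experiment and are never reset; adaptation to the mid-experiment change is
# the job of the surprise system, not of novelty.

#' State-visit counts
#'
#' @param n_states Number of states (default 11, including the goal).
#' @return A `state_counts` object: integer counts per state plus the total
#'   number of observations `t`.
#' @export
state_counts <- function(n_states = 11L) {
  structure(list(counts = integer(n_states), t = 0L, n_states = n_states),
            class = "state_counts")
}

#' Laplace-smoothed observation frequency of a state
#'
#' Returns `(C_s + 1) / (t + n_states)`: the empirical frequency of the
#' state under a uniform prior of one pseudo-observation per state. The
#' values over all states form a proper probability distribution.
#'
#' @param counts A `state_counts` object.
#' @param s State label (the goal state is a valid argument).
#' @export
observation_frequency <- function(counts, s) {
  stopifnot(inherits(counts, "state_counts"))
  if (any(s < 1L) || any(s > counts$n_states)) stop("unknown state label: ", s)
  (counts$counts[s] + 1) / (counts$t + counts$n_states)
}

#' Novelty of a state (nats)
#'
#' The negative natural logarithm of [observation_frequency()]. Strictly
#' positive, and strictly decreasing in the state's count at fixed total.
#'
#' @inheritParams observation_frequency
#' @export
novelty <- function(counts, s) -log(observation_frequency(counts, s))

#' Record one observation of a state
#'
#' Increments the state's count and the total by one. The novelty reward of
#' a transition is always read from the counts *before* this update.
#'
#' @inheritParams observation_frequency
#' @export
record_observation <- function(counts, s) {
  stopifnot(inherits(counts, "state_counts"))
  if (s < 1L || s > counts$n_states) stop("unknown state label: ", s)
  counts$counts[s] <- counts$counts[s] + 1L
  counts$t <- counts$t + 1L
  counts
}
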