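# Closed-loop reward feedback: rank the current trial's movement time
# against the participant's last 20 trials and convert the rank percentile
# to points (0-5p). Because the comparison set tracks recent performance,
# the criterion adapts: steady improvement does not saturate the payout.

#' Create a reward comparison state
#'
#' Holds the rolling buffer of the most recent movement times (capacity 20,
#' oldest evicted first) that the closed-loop feedback ranks against.
#'
#' @param mts Initial movement times (s), oldest first.
#' @param capacity Buffer capacity.
#' @return List of class `reward_state` with `buffer`, `capacity`.
#' @export
reward_state <- function(mts = numeric(), capacity = 20L) {
  stopifnot(capacity >= 1)
  n <- length(mts)
  if (n > capacity) mts <- mts[(n - capacity + 1):n]
  structure(list(buffer = as.numeric(mts), capacity = as.integer(capacity)),
            class = "reward_state")
}

#' @export
print.reward_state <- function(x, ...) {
  cat(sprintf("reward state: %d/%d MTs buffered%s\n", length(x$buffer),
              x$capacity,
              if (length(x$buffer) < x$capacity) " (warm-up)" else ""))
  invisible(x)
}

#' Score one trial against the reward buffer
#'
#' The current movement time is ranked against the buffered MTs. Its rank
#' percentile is `100 * (# buffered MTs strictly slower) / buffer length`
#' (ties favour the participant: an equal MT does not count as slower).
#' Points by percentile band: >= 90 gives 5p, 80-90 gives 4p, 60-80 gives
#' 3p, 40-60 gives 2p, 20-40 gives 1p, < 20 gives 0p. With
#' `rule = "topbottom3"` the extreme bands are instead the top three and
#' bottom three ranks of a full 20-trial buffer (the alternative reading of
#' the design's "top three / bottom three" description).
#'
#' @param state A [reward_state()].
#' @param mt Movement time of the current trial (s, > 0).
#' @param rule `"percentile"` (default) or `"topbottom3"`.
#' @return List of class `feedback_result`: `points` (0..5), `percentile`,
#'   `rank` (1 = fastest among buffer + current), `warmup` (TRUE if the
#'   buffer held fewer than `capacity` values).
#' @export
score_trial <- function(state, mt, rule = c("percentile", "topbottom3")) {
  rule <- match.arg(rule)
  if (!is.finite(mt) || mt <= 0) stop("movement time must be positive")
  n <- length(state$buffer)
  if (n < 1) stop("empty reward buffer: seed the state before scoring")
  slower <- sum(state$buffer > mt)
  p <- 100 * slower / n
  points <- percentile_points(p)
  if (rule == "topbottom3") {
    if (n - slower <= 2) points <- 5L       # faster than all but <= 2: top 3
    else if (slower <= 2) points <- 0L      # bottom 3 ranks
    else points <- percentile_points(p)
  }
  structure(list(points = points, percentile = p,
                 rank = n - slower + 1L, warmup = n < state$capacity),
            class = "feedback_result")
}

percentile_points <- function(p) {
  if (p >= 90) 5L
  else if (p >= 80) 4L
  else if (p >= 60) 3L
  else if (p >= 40) 2L
  else if (p >= 20) 1L
  else 0L
}

#' @export
print.feedback_result <- function(x, ...) {
  cat(sprintf("%dp out of 5p (percentile %.0f, rank %d%s)\n", x$points,
              x$percentile, x$rank, if (x$warmup) ", warm-up" else ""))
  invisible(x)
}

#' Append a movement time to the reward buffer
#'
#' FIFO update: the new MT is appended and the oldest evicted once the
#' buffer exceeds capacity.
#'
#' @param state A [reward_state()].
#' @param mt Movement time (s).
#' @return Updated `reward_state`.
#' @export
update_state <- function(state, mt) {
  buf <- c(state$buffer, mt)
  n <- length(buf)
  if (n > state$capacity) buf <- buf[(n - state$capacity + 1):n]
  state$buffer <- buf
  state
}

#' Seed the reward state at a block boundary
#'
#' When a new experimental block starts, the first trials are compared to
#' the last 20 trials of the previously completed block.
#'
#' @param prev_block Movement times of the previous block, in order.
#' @param capacity Buffer capacity.
#' @return A `reward_state`; if fewer than `capacity` MTs are available all
#'   are used and scoring reports `warmup = TRUE`.
#' @export
seed_block_boundary <- function(prev_block, capacity = 20L) {
  reward_state(prev_block, capacity)
}

#' Replay closed-loop feedback over a block of trials
#'
#' Scores each movement time against the rolling buffer, then appends it,
#' reproducing the feedback a participant would have seen.
#'
#' @param mts Movement times of the block, in order.
#' @param state Initial [reward_state()] (e.g. from
#'   [seed_block_boundary()]).
#' @param rule Passed to [score_trial()].
#' @return data.frame with `trial`, `mt`, `points`, `percentile`, `warmup`.
#' @export
replay_reward <- function(mts, state = reward_state(), rule = "percentile") {
  out <- data.frame(trial = seq_along(mts), mt = mts, points = NA_integer_,
                    percentile = NA_real_, warmup = NA)
  for (i in seq_along(mts)) {
    if (length(state$buffer) >= 1) {
      fb <- score_trial(state, mts[i], rule)
      out$points[i] <- fb$points
      out$percentile[i] <- fb$percentile
      out$warmup[i] <- fb$warmup
    } else {
      out$warmup[i] <- TRUE
    }
    state <- update_state(state, mts[i])
  }
  out
}
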