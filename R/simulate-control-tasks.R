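# Simulators for the positive-control tasks: the probabilistic Go/NoGo
# learning phase and the verbal working-memory task.

#' Simulate the probabilistic Go/NoGo learning phase
#'
#' Four stimuli, two associated with rewards and two with losses, each
#' presented 10 times in random order (40 trials). Responses come from a
#' Rescorla-Wagner learner: each stimulus carries a value Q updated only
#' after Go responses (feedback is only given after Go), with separate
#' learning rates for wins (`lr_win`) and losses (`lr_loss`) so a
#' haloperidol-like asymmetry (enhanced positive-feedback, impaired
#' negative-feedback learning) can be injected. Go probability is
#' `plogis(beta * Q + go_bias)`.
#'
#' @param profile A [participant_profile()] (identifies the participant).
#' @param config A [sim_config()]; its `gonogo` list supplies
#'   `p_win_reward`, `p_win_loss`, `lr_win`, `lr_loss`, `beta`, `go_bias`.
#' @param seed Optional integer seed.
#' @param n_reps Presentations per stimulus.
#' @return data.frame: `trial`, `stimulus` (1..4), `stim_type`
#'   ("reward"/"loss"), `go` (logical), `outcome` (+1 win, -1 loss, NA after
#'   No-Go).
#' @export
simulate_gonogo <- function(profile, config = sim_config(), seed = NULL,
                            n_reps = 10L) {
  gg <- config$gonogo
  stim_type <- c("reward", "reward", "loss", "loss")
  p_win <- c(gg$p_win_reward, gg$p_win_reward, gg$p_win_loss, gg$p_win_loss)
  with_seed(seed, {
    order_ <- sample(rep(1:4, n_reps))
    q <- rep(0, 4)
    n <- length(order_)
    go <- logical(n)
    outcome <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      s <- order_[i]
      p_go <- stats::plogis(gg$beta * q[s] + gg$go_bias)
      go[i] <- stats::runif(1) < p_go
      if (go[i]) {
        win <- stats::runif(1) < p_win[s]
        outcome[i] <- if (win) 1 else -1
        lr <- if (win) gg$lr_win else gg$lr_loss
        q[s] <- q[s] + lr * (outcome[i] - q[s])
      }
    }
    data.frame(trial = seq_len(n), stimulus = order_,
               stim_type = stim_type[order_], go = go, outcome = outcome)
  })
}

#' Simulate the verbal working-memory task
#'
#' 60 recognition trials over consonant arrays of length 5 to 9 (12 trials
#' per length). The probability of a correct response decreases with array
#' length and increases with the participant's latent ability `wm_true`.
#'
#' @param profile A [participant_profile()] (supplies `wm_true`).
#' @param config A [sim_config()] (unused fields reserved).
#' @param seed Optional integer seed.
#' @param n_per_length Trials per array length.
#' @return List: `trials` (data.frame `length`, `correct`), `by_length`
#'   (accuracy per length, %), `score` (% correct over lengths 7-9, the
#'   quantity used for the working-memory median split).
#' @export
simulate_vwm <- function(profile, config = sim_config(), seed = NULL,
                         n_per_length = 12L) {
  lengths_ <- rep(5:9, each = n_per_length)
  with_seed(seed, {
    # logistic performance: ~93% at length 5 down to ~65% at length 9 for an
    # average participant, shifted by latent ability
    p <- stats::plogis(2.6 + profile$wm_true - 0.5 * (lengths_ - 5))
    correct <- stats::runif(length(lengths_)) < p
    by_length <- 100 * tapply(correct, lengths_, mean)
    list(trials = data.frame(length = lengths_, correct = correct),
         by_length = by_length,
         score = 100 * mean(correct[lengths_ >= 7]))
  })
}
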