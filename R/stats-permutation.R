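# Row-shuffle permutation test for trial windows of significant group
# difference.

#' Permutation test for significant trial windows
#'
#' For each analysis trial, computes the Welch two-sample t statistic
#' between two groups of per-participant trial series, builds a per-trial
#' null distribution by shuffling the participant rows (group labels)
#' `n_perm` times, and flags a trial as significant when its observed |t|
#' exceeds the (1 - alpha) quantile of that trial's permutation
#' distribution (the identity permutation is included in the null set, so
#' the test is valid at finite `n_perm`). Maximal runs of significant
#' trials are returned as windows.
#'
#' @param series_a,series_b Numeric matrices, participants x trials,
#'   aligned on the same analysis trial numbers.
#' @param n_perm Number of label shuffles (default 5000).
#' @param alpha Per-trial significance level.
#' @param seed Optional integer seed for the shuffles.
#' @return Object of class `window_test`: `t_obs` (per-trial observed t),
#'   `threshold` (per-trial |t| quantile), `significant` (logical),
#'   `windows` (data.frame `start`, `end`, `length`), `alpha`, `n_perm`.
#' @export
permutation_window_test <- function(series_a, series_b, n_perm = 5000,
                                    alpha = 0.05, seed = NULL) {
  series_a <- as.matrix(series_a)
  series_b <- as.matrix(series_b)
  if (ncol(series_a) != ncol(series_b))
    stop("the two groups must be aligned on the same trials")
  n1 <- nrow(series_a)
  n2 <- nrow(series_b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 participants")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution")

  welch_t <- function(x, y) {
    m1 <- colMeans(x); m2 <- colMeans(y)
    v1 <- colMeans(x^2) - m1^2; v2 <- colMeans(y^2) - m2^2
    v1 <- v1 * nrow(x) / (nrow(x) - 1); v2 <- v2 * nrow(y) / (nrow(y) - 1)
    (m1 - m2) / sqrt(v1 / nrow(x) + v2 / nrow(y))
  }

  X <- rbind(series_a, series_b)
  t_obs <- welch_t(series_a, series_b)
  perm_abs <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, ncol(X))
    for (p in seq_len(n_perm)) {
      lab <- sample.int(n1 + n2, n1)
      out[p, ] <- abs(welch_t(X[lab, , drop = FALSE],
                              X[-lab, , drop = FALSE]))
    }
    out
  })
  # identity permutation joins the null set
  null_abs <- rbind(abs(t_obs), perm_abs)
  threshold <- apply(null_abs, 2, stats::quantile, probs = 1 - alpha,
                     names = FALSE, type = 7)
  sig <- abs(t_obs) > threshold
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  windows <- data.frame(start = starts[runs$values],
                        end = ends[runs$values])
  windows$length <- windows$end - windows$start + 1L
  structure(list(t_obs = t_obs, threshold = threshold, significant = sig,
                 windows = windows, alpha = alpha, n_perm = n_perm),
            class = "window_test")
}

#' @export
print.window_test <- function(x, ...) {
  cat(sprintf("row-shuffle permutation test: %d trials, %d permutations, alpha %.3f\n",
              length(x$t_obs), x$n_perm, x$alpha))
  if (nrow(x$windows) == 0) {
    cat("  no significant trial windows\n")
  } else {
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("  significant window: trials %d-%d (%d trials)\n",
                  x$windows$start[i], x$windows$end[i], x$windows$length[i]))
  }
  invisible(x)
}
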