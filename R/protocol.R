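# Experiment schedule and pre-analysis exclusion filters.

#' Build the trial schedule for one day
#'
#' Days 1 and 2: Baseline (10 trials), Training (200), then two post
#' assessments of 20 trials each (one rewarded, one not, order
#' counterbalanced). Day 7: the two post assessments only, 25 trials each.
#' A secondary (dual) task is scheduled on every 10th Training trial and
#' every 5th trial of all other phases, counted from trial 1 of the phase;
#' those trials are later removed from analysis.
#'
#' @param day 1, 2 or 7.
#' @param post_order `"RewFirst"` or `"NoRewFirst"`.
#' @param include_baseline Include the Baseline phase (days 1/2).
#' @param include_familiarisation Prepend the 20-trial familiarisation block
#'   (day 1 only; always flagged `exclude_always`).
#' @return data.frame of class `schedule`: `phase`, `phase_trial`,
#'   `reward_phase` (logical: feedback given in rewarded groups),
#'   `dual_task`, `exclude_always`.
#' @export
build_schedule <- function(day, post_order = c("RewFirst", "NoRewFirst"),
                           include_baseline = TRUE,
                           include_familiarisation = FALSE) {
  post_order <- match.arg(post_order)
  if (!day %in% c(1, 2, 7)) stop("invalid day: ", day, " (must be 1, 2 or 7)")
  posts <- if (post_order == "RewFirst") c("PostRew", "PostNoRew")
           else c("PostNoRew", "PostRew")
  n_post <- if (day == 7) 25L else 20L
  phases <- list()
  if (include_familiarisation && day == 1)
    phases$Familiarisation <- list(n = 20L, reward = FALSE, cadence = 5L,
                                   excl = TRUE)
  if (day %in% c(1, 2) && include_baseline)
    phases$Baseline <- list(n = 10L, reward = FALSE, cadence = 5L,
                            excl = FALSE)
  if (day %in% c(1, 2))
    phases$Training <- list(n = 200L, reward = TRUE, cadence = 10L,
                            excl = FALSE)
  for (ph in posts)
    phases[[ph]] <- list(n = n_post, reward = ph == "PostRew", cadence = 5L,
                         excl = FALSE)
  out <- do.call(rbind, lapply(names(phases), function(nm) {
    p <- phases[[nm]]
    tr <- seq_len(p$n)
    data.frame(phase = nm, phase_trial = tr, reward_phase = p$reward,
               dual_task = tr %% p$cadence == 0, exclude_always = p$excl)
  }))
  class(out) <- c("schedule", "data.frame")
  attr(out, "day") <- day
  out
}

#' Exclude participants with outlying Baseline movement times
#'
#' Participants whose mean Baseline MT exceeds the threshold (default 8.5 s)
#' are removed before analysis.
#'
#' @param baseline_mts data.frame with `participant_id` and `mt` (one row
#'   per Baseline trial), or a named list of per-participant MT vectors.
#' @param threshold Mean-MT cutoff in seconds.
#' @return List of class `exclusion_report`: `removed_participants`
#'   (data.frame id / mean_mt / reason), `retained_participants`,
#'   `threshold`.
#' @export
exclude_baseline_outlier_participants <- function(baseline_mts,
                                                  threshold = 8.5) {
  if (!is.data.frame(baseline_mts)) {
    baseline_mts <- data.frame(
      participant_id = rep(names(baseline_mts),
                           lengths(baseline_mts)),
      mt = unlist(baseline_mts, use.names = FALSE))
  }
  means <- tapply(baseline_mts$mt, baseline_mts$participant_id, mean)
  bad <- names(means)[means > threshold]
  rep <- list(
    removed_participants = data.frame(
      participant_id = bad,
      mean_mt = as.numeric(means[bad]),
      reason = rep("baseline_mean_mt_above_threshold", length(bad))),
    retained_participants = setdiff(names(means), bad),
    threshold = threshold)
  class(rep) <- "exclusion_report"
  rep
}

#' Exclude trials and renumber for analysis
#'
#' Drops all dual-task trials, any trial flagged `exclude_always`, and
#' trials with movement time above `mt_cap` (default 10 s), then assigns a
#' dense, order-preserving analysis trial number within each
#' participant x day x phase (Training becomes 1..180 after the 20
#' scheduled dual-task removals).
#'
#' @param trial_table data.frame with at least `participant_id`, `day`,
#'   `phase`, `trial`, `dual_task`, `mt`.
#' @param mt_cap Movement-time cap in seconds.
#' @return List of class `trial_exclusions`: `trials` (filtered table with
#'   `analysis_trial`), `report` (counts by reason, retained, input).
#' @export
exclude_trials <- function(trial_table, mt_cap = 10) {
  stopifnot(all(c("participant_id", "day", "phase", "trial",
                  "dual_task", "mt") %in% names(trial_table)))
  n_in <- nrow(trial_table)
  always <- if ("exclude_always" %in% names(trial_table))
    trial_table$exclude_always else rep(FALSE, n_in)
  dual <- trial_table$dual_task & !always
  overlong <- trial_table$mt > mt_cap & !trial_table$dual_task & !always
  keep <- !(dual | overlong | always)
  kept <- trial_table[keep, , drop = FALSE]
  o <- order(kept$participant_id, kept$day, kept$phase, kept$trial)
  kept <- kept[o, , drop = FALSE]
  grp <- interaction(kept$participant_id, kept$day, kept$phase, drop = TRUE)
  kept$analysis_trial <- stats::ave(seq_len(nrow(kept)), grp,
                                    FUN = seq_along)
  rownames(kept) <- NULL
  res <- list(trials = kept,
              report = list(input = n_in,
                            removed = c(dual_task = sum(dual),
                                        overlong = sum(overlong),
                                        familiarisation = sum(always)),
                            retained = nrow(kept),
                            mt_cap = mt_cap))
  class(res) <- "trial_exclusions"
  res
}

#' @export
print.trial_exclusions <- function(x, ...) {
  r <- x$report
  cat(sprintf("trial exclusions: %d in, %d retained\n", r$input, r$retained))
  cat(sprintf("  removed: %d dual-task, %d overlong (> %.0f s), %d familiarisation\n",
              r$removed[["dual_task"]], r$removed[["overlong"]], r$mt_cap,
              r$removed[["familiarisation"]]))
  invisible(x)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("participant exclusions (baseline mean MT > %.1f s): %d removed, %d retained\n",
              x$threshold, nrow(x$removed_participants),
              length(x$retained_participants)))
  if (nrow(x$removed_participants)) print(x$removed_participants)
  invisible(x)
}
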