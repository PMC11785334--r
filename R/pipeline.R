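# End-to-end pipeline: simulate -> kinematics -> exclusions -> reward
# replay -> statistics, persisted to a run directory with a manifest.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()].
#' @param sigma Gaussian smoothing width for speed profiles (samples).
#' @param mt_cap Trial-exclusion movement-time cap (s).
#' @param baseline_threshold Participant-exclusion baseline mean MT cap (s).
#' @param reward_rule Reward-bin interpretation, see [score_trial()].
#' @param n_perm Permutations for the trial-window test.
#' @param alpha Significance level.
#' @param seed Master seed (also seeds `sim` unless it carries its own).
#' @param profile `"demo"` (small cohort, day 1 only, quick) or `"full"`
#'   (92-participant scale, all days, 5000 permutations).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, sigma = 2, mt_cap = 10,
                       baseline_threshold = 8.5,
                       reward_rule = "percentile",
                       n_perm = NULL, alpha = 0.05, seed = 1L,
                       profile = c("demo", "full")) {
  profile <- match.arg(profile)
  if (is.null(sim))
    sim <- if (profile == "full")
      sim_config(n_per_group = 23, days = c(1, 2, 7), seed = seed)
    else sim_config(n_per_group = 2, days = 1, seed = seed)
  if (is.null(n_perm)) n_perm <- if (profile == "full") 5000 else 200
  structure(list(sim = sim, sigma = sigma, mt_cap = mt_cap,
                 baseline_threshold = baseline_threshold,
                 reward_rule = reward_rule, n_perm = n_perm, alpha = alpha,
                 seed = seed, profile = profile),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort (trajectories plus Go/NoGo and verbal-memory
#' behaviour), measures per-trial kinematics, replays the closed-loop
#' reward feedback over Training for rewarded participants, applies the
#' participant and trial exclusion rules, classifies working memory by
#' median split, and runs the statistical analyses: trial-level LMMs with
#' marginal slopes and pairwise z-tests per dependent variable, a
#' permutation trial-window test between the rewarded drug groups, the
#' post-assessment mixed ANOVA, and the Go/NoGo positive control. All
#' tables are written as CSV and a JSON manifest records the configuration
#' and output hashes; a rerun with the same config is identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` for no
#'   persistence.
#' @return List of class `pipeline_run` with all intermediate and final
#'   results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stage <- "simulate"
  res <- list(config = config)
  tryCatch({
    cohort <- simulate_cohort(config$sim)
    res$trials_raw <- cohort$trials

    stage <- "control_tasks"
    seeds_g <- derive_seeds(config$sim$seed, length(cohort$profiles), 7L)
    seeds_v <- derive_seeds(config$sim$seed, length(cohort$profiles), 8L)
    ra_rows <- vwm_rows <- list()
    for (i in seq_along(cohort$profiles)) {
      p <- cohort$profiles[[i]]
      gg <- simulate_gonogo(p, config$sim, seed = seeds_g[[i]])
      ra <- response_accuracy(gg)
      vw <- simulate_vwm(p, config$sim, seed = seeds_v[[i]])
      ra_rows[[i]] <- data.frame(participant_id = p$id,
                                 drug_group = p$drug_group,
                                 reward_group = p$reward_group,
                                 learn_plus = ra$learn_plus,
                                 learn_minus = ra$learn_minus)
      vwm_rows[[i]] <- data.frame(participant_id = p$id, score = vw$score)
    }
    ra_tab <- do.call(rbind, ra_rows)
    vwm_tab <- do.call(rbind, vwm_rows)
    wm <- wm_median_split(vwm_tab)
    res$wm <- wm
    ra_tab$wm_class <- wm$wm_class[match(ra_tab$participant_id,
                                         wm$participant_id)]
    res$response_accuracy <- ra_tab

    stage <- "reward_replay"
    trials <- cohort$trials
    trials$wm_class <- wm$wm_class[match(trials$participant_id,
                                         wm$participant_id)]
    trials$points <- NA_integer_
    for (pid in unique(trials$participant_id)) {
      sel <- trials$participant_id == pid & trials$reward_group == "Rew"
      for (dd in unique(trials$day[sel])) {
        prev <- NULL
        for (ph in unique(trials$phase[sel & trials$day == dd])) {
          rows <- which(sel & trials$day == dd & trials$phase == ph)
          if (!length(rows)) next
          if (trials$reward_phase[rows[1]]) {
            st <- if (is.null(prev)) reward_state()
                  else seed_block_boundary(prev)
            fb <- replay_reward(trials$mt[rows], st, config$reward_rule)
            trials$points[rows] <- fb$points
          }
          prev <- trials$mt[rows]
        }
      }
    }

    stage <- "exclusions"
    base <- trials[trials$phase == "Baseline" & trials$day == 1, ]
    pexc <- if (nrow(base))
      exclude_baseline_outlier_participants(
        base[, c("participant_id", "mt")], config$baseline_threshold)
    else list(removed_participants = data.frame(),
              retained_participants = unique(trials$participant_id))
    res$participant_exclusions <- pexc
    trials <- trials[trials$participant_id %in% pexc$retained_participants, ]
    texc <- exclude_trials(trials, config$mt_cap)
    res$trial_exclusions <- texc$report
    analysis <- texc$trials
    res$trials <- analysis

    stage <- "lmm"
    tr1 <- analysis[analysis$phase == "Training" & analysis$day == 1, ]
    res$lmm <- list()
    for (dv in c("vmax_mean", "fi_sum", "mt")) {
      fit <- fit_trial_lmm(tr1, dv)
      sl <- marginal_slopes(fit, c("Reward", "Drug"))
      res$lmm[[dv]] <- list(coefficients = fit$coefficients,
                            fallback = fit$fallback,
                            slopes = sl,
                            pairwise = pairwise_slope_ztests(sl))
    }

    stage <- "permutation"
    mk_mat <- function(d) {
      w <- stats::reshape(d[, c("participant_id", "analysis_trial",
                                "vmax_mean")],
                          idvar = "participant_id",
                          timevar = "analysis_trial", direction = "wide")
      as.matrix(w[, -1])
    }
    ga <- tr1[tr1$reward_group == "Rew" & tr1$drug_group == "Halo", ]
    gb <- tr1[tr1$reward_group == "Rew" & tr1$drug_group == "Ctrl", ]
    if (length(unique(ga$participant_id)) >= 2 &&
        length(unique(gb$participant_id)) >= 2) {
      ma <- mk_mat(ga)
      mb <- mk_mat(gb)
      ok <- seq_len(min(ncol(ma), ncol(mb)))
      ok <- ok[colSums(is.na(ma[, ok, drop = FALSE])) == 0 &
                 colSums(is.na(mb[, ok, drop = FALSE])) == 0]
      res$windows <- permutation_window_test(
        ma[, ok, drop = FALSE], mb[, ok, drop = FALSE],
        n_perm = config$n_perm,
        alpha = config$alpha,
        seed = derive_seeds(config$seed, 1, 9L)[[1]])
    }

    stage <- "post_assessment"
    post1 <- analysis[analysis$day == 1 &
                        analysis$phase %in% c("PostRew", "PostNoRew"), ]
    if (nrow(post1)) res$post_anova <- post_assessment_anova(post1,
                                                            "vmax_mean")

    stage <- "positive_control"
    if (min(table(ra_tab$wm_class[ra_tab$wm_class == "low"])) >= 0 &&
        sum(ra_tab$wm_class == "low" & ra_tab$drug_group == "Halo") >= 2 &&
        sum(ra_tab$wm_class == "low" & ra_tab$drug_group == "Ctrl") >= 2)
      res$positive_control <- positive_control_anova(ra_tab, "low")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  class(res) <- "pipeline_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wcsv(res$trials_raw, "trials_raw.csv")
  wcsv(res$trials, "trials_analysis.csv")
  wcsv(res$response_accuracy, "response_accuracy.csv")
  wcsv(res$wm, "wm_split.csv")
  for (dv in names(res$lmm)) {
    wcsv(as.data.frame(res$lmm[[dv]]$coefficients), sprintf("lmm_%s.csv", dv))
    wcsv(res$lmm[[dv]]$slopes, sprintf("slopes_%s.csv", dv))
    wcsv(res$lmm[[dv]]$pairwise, sprintf("pairwise_%s.csv", dv))
  }
  if (!is.null(res$windows))
    wcsv(data.frame(trial = seq_along(res$windows$t_obs),
                    t = res$windows$t_obs,
                    threshold = res$windows$threshold,
                    significant = res$windows$significant),
         "permutation_windows.csv")
  if (!is.null(res$post_anova)) wcsv(res$post_anova$anova, "post_anova.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("seqreach")),
    seed = res$config$seed,
    profile = res$config$profile,
    n_per_group = res$config$sim$n_per_group,
    trial_exclusions = res$trial_exclusions,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run (profile %s, seed %s): %d analysis trials, %d participants\n",
              x$config$profile, x$config$seed, nrow(x$trials),
              length(unique(x$trials$participant_id))))
  for (dv in names(x$lmm)) {
    cat(sprintf("\nmarginal trial slopes for %s:\n", dv))
    print(x$lmm[[dv]]$slopes, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$windows)) print(x$windows)
  invisible(x)
}
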