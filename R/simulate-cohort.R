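# Cohort-level simulation: configuration, group effects, and generation of
# all trials over the experimental protocol.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort: sample size, trial counts
#' (delegated to the protocol schedule), group effects on the vigour and
#' fusion learning slopes, motor noise, and the sampling geometry of the
#' tracker. The seed fully determines all outputs.
#'
#' Group effects are expressed as the per-trial learning slope of each
#' Reward x Drug cell for segment peak speed (`vigour_slopes`, cm/s per
#' trial) and of each Drug x WM cell for the transition trough fraction
#' (`fusion_slopes`, 1/trial). Defaults follow the qualitative pattern this
#' design is built to detect: the rewarded placebo group gains vigour
#' fastest, the rewarded haloperidol group is flat, unrewarded groups sit in
#' between; fusion improves in all groups but least in high-WM haloperidol
#' participants, with a small additive reward benefit.
#'
#' @param n_per_group Participants per Reward x Drug cell.
#' @param days Days simulated (subset of 1, 2, 7).
#' @param vigour0_mean,vigour0_sd Baseline peak speed distribution (cm/s).
#' @param vigour_slopes Named numeric, per-trial vigour slope by group
#'   (`CtrlR`, `HaloR`, `CtrlNR`, `HaloNR`).
#' @param vigour_slope_sd Between-participant sd of the vigour slope.
#' @param fusion0_mean,fusion0_sd Baseline trough-fraction distribution.
#' @param fusion_slopes Named numeric, per-trial trough-fraction slope by
#'   Drug x WM cell (`Ctrl_high`, `Ctrl_low`, `Halo_high`, `Halo_low`).
#' @param fusion_reward_bonus Additive trough-fraction slope for rewarded
#'   participants (1/trial).
#' @param fusion_slope_sd Between-participant sd of the fusion slope.
#' @param fusion_cap Upper clamp of the profile-driven trough fraction.
#' @param noise_sd Positional noise sd (cm).
#' @param dwell_floor Minimum stationary via dwell at zero fusion (s).
#' @param reaction_time Stationary lead-in before movement onset (s).
#' @param tail_time Stationary tail after the final target (s).
#' @param sampling_rate Tracker sampling rate (Hz).
#' @param outer_order Visit order of the four outer targets.
#' @param include_familiarisation Generate the 20-trial familiarisation
#'   block on day 1 (always flagged out of analysis).
#' @param gonogo See [simulate_gonogo()]: list of win probabilities and
#'   learner settings.
#' @param seed Master seed; each participant gets an independent derived
#'   stream so cohort growth does not reshuffle existing participants.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 4,
                       days = c(1, 2, 7),
                       vigour0_mean = 21, vigour0_sd = 3.5,
                       vigour_slopes = c(CtrlR = 0.024, HaloR = -0.005,
                                         CtrlNR = 0.013, HaloNR = 0.013),
                       vigour_slope_sd = 0.01,
                       fusion0_mean = 0.12, fusion0_sd = 0.04,
                       fusion_slopes = c(Ctrl_high = 5e-4, Ctrl_low = 2.9e-4,
                                         Halo_high = 1.3e-4, Halo_low = 3.4e-4),
                       fusion_reward_bonus = 2e-4,
                       fusion_slope_sd = 1.5e-4,
                       fusion_cap = 0.95,
                       noise_sd = 0.03,
                       dwell_floor = 0.15,
                       reaction_time = 0.3,
                       tail_time = 0.3,
                       sampling_rate = 110,
                       outer_order = 1:4,
                       include_familiarisation = FALSE,
                       gonogo = list(p_win_reward = 0.8, p_win_loss = 0.2,
                                     lr_win = 0.3, lr_loss = 0.3,
                                     beta = 4, go_bias = 0.3),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

group_key <- function(reward_group, drug_group) {
  paste0(drug_group, ifelse(reward_group == "Rew", "R", "NR"))
}

#' Draw the participant profiles of a cohort
#'
#' Four groups (Rew/NoRew x Halo/Ctrl), `n_per_group` each. Latent
#' working-memory ability is drawn N(0, 1); the WM class used by the
#' analysis comes later from the simulated memory task and a median split.
#'
#' @param config A [sim_config()].
#' @return List of [participant_profile()] objects, with `wm_latent_class`
#'   ("high"/"low" by the sign of `wm_true`) attached for effect injection.
#' @export
cohort_profiles <- function(config = sim_config()) {
  groups <- expand.grid(reward_group = c("Rew", "NoRew"),
                        drug_group = c("Halo", "Ctrl"),
                        stringsAsFactors = FALSE)
  n_total <- nrow(groups) * config$n_per_group
  profiles <- vector("list", n_total)
  i <- 0L
  for (g in seq_len(nrow(groups))) {
    gk <- group_key(groups$reward_group[g], groups$drug_group[g])
    # seeds keyed by (group, position within group): growing the cohort
    # never reshuffles existing participants
    seeds <- derive_seeds(config$seed, config$n_per_group, stream = g)
    for (k in seq_len(config$n_per_group)) {
      i <- i + 1L
      profiles[[i]] <- with_seed(seeds[[k]], {
        wm <- stats::rnorm(1)
        wm_class <- if (wm >= 0) "high" else "low"
        fkey <- paste0(groups$drug_group[g], "_", wm_class)
        fslope <- config$fusion_slopes[[fkey]] +
          (groups$reward_group[g] == "Rew") * config$fusion_reward_bonus +
          stats::rnorm(1, 0, config$fusion_slope_sd)
        p <- participant_profile(
          id = sprintf("%s_%02d", gk, k),
          reward_group = groups$reward_group[g],
          drug_group = groups$drug_group[g],
          vigour0 = max(5, stats::rnorm(1, config$vigour0_mean,
                                        config$vigour0_sd)),
          vigour_slope = config$vigour_slopes[[gk]] +
            stats::rnorm(1, 0, config$vigour_slope_sd),
          fusion0 = clamp(stats::rnorm(1, config$fusion0_mean,
                                       config$fusion0_sd), 0, 0.5),
          fusion_slope = fslope,
          noise_sd = config$noise_sd,
          wm_true = wm)
        p$wm_latent_class <- wm_class
        p$trial_seed <- derive_seeds(config$seed, config$n_per_group,
                                     stream = 50L + g)[[k]]
        p
      })
    }
  }
  profiles
}

#' Simulate a full cohort over the protocol
#'
#' Generates every trial of every participant across the scheduled days and
#' phases, runs the kinematic pipeline on each trajectory, and returns a
#' tidy per-trial table. Learning (the vigour/fusion slopes) accrues over
#' Training trials; Baseline trials are at baseline parameters and Post
#' trials retain the end-of-Training state (day 2 continues from day 1's
#' 200 Training trials).
#'
#' @param config A [sim_config()].
#' @param layout A `target_layout`.
#' @param keep_trajectories Return the trajectory objects as well (memory
#'   heavy; off by default).
#' @return List of class `cohort`: `profiles`, `trials` (data.frame with
#'   participant/group columns, day, phase, trial-in-phase, dual_task flag
#'   and the kinematic metrics), and optionally `trajectories`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            layout = make_target_layout(),
                            keep_trajectories = FALSE) {
  stopifnot(config$n_per_group >= 1)
  profiles <- cohort_profiles(config)
  sequence <- trial_sequence(layout, config$outer_order)
  rows <- list()
  trajs <- if (keep_trajectories) list() else NULL
  for (p in profiles) {
    learned <- 0L # cumulative Training trials completed
    trial_seeds_used <- 0L
    for (day in sort(config$days)) {
      sched <- build_schedule(day,
        post_order = if (p$reward_group == "Rew") "RewFirst" else "NoRewFirst",
        include_familiarisation = config$include_familiarisation && day == 1)
      for (i in seq_len(nrow(sched))) {
        ph <- sched$phase[i]
        # learning index driving the slopes: frozen outside Training
        tr_index <- if (ph == "Training") learned + 1L else max(1L, learned)
        trial_seeds_used <- trial_seeds_used + 1L
        sd_i <- if (is.null(p$trial_seed)) NULL else
          ((p$trial_seed + trial_seeds_used * 2971) %% 2147483629) + 1
        traj <- simulate_trajectory(p, tr_index, layout, config,
                                    seed = sd_i,
                                    phase = ph, day = day,
                                    dual_task = sched$dual_task[i])
        km <- trial_kinematics(traj, layout, sequence)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = p$id,
          reward_group = p$reward_group,
          drug_group = p$drug_group,
          day = day, phase = ph, trial = sched$phase_trial[i],
          dual_task = sched$dual_task[i],
          reward_phase = sched$reward_phase[i],
          mt = km$mt, reaction_time = km$reaction_time,
          vmax_mean = km$vmax_mean, fi_sum = km$fi_sum,
          n_clamped = km$n_clamped)
        if (keep_trajectories) trajs[[length(trajs) + 1L]] <- traj
        if (ph == "Training") learned <- learned + 1L
      }
    }
  }
  out <- list(profiles = profiles, trials = do.call(rbind, rows),
              config = config)
  if (keep_trajectories) out$trajectories <- trajs
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d participants, %d trials (days %s)\n",
              length(x$profiles), nrow(x$trials),
              paste(sort(unique(x$trials$day)), collapse = ", ")))
  print(table(group = with(x$trials,
                           tapply(group_key(reward_group, drug_group),
                                  participant_id, `[`, 1))))
  invisible(x)
}

#' Simulate a per-trial metrics table directly
#'
#' Draws the analysis-ready trial table (one row per participant x trial,
#' with `vmax_mean`, `fi_sum` and `mt`) straight from the linear model the
#' mixed-model analysis assumes: per-participant random intercepts and
#' random trial slopes around group mean slopes, plus residual noise. This
#' is the generator used for statistical calibration (slope-sign recovery,
#' permutation-test power) where thousands of cohorts are needed; the
#' trajectory-level generator is validated separately against the
#' kinematics module.
#'
#' @param n_per_group Participants per Reward x Drug cell.
#' @param n_trials Analysis trials per participant.
#' @param vigour_slopes,fusion_slopes,fusion_reward_bonus As [sim_config()].
#' @param vigour0_mean,vigour0_sd,vigour_slope_sd As [sim_config()].
#' @param fi0_mean,fi0_sd,fi_slope_sd Baseline/slope variation of the trial
#'   fusion-index sum.
#' @param mt0_mean,mt0_sd Baseline movement time (s).
#' @param mt_slopes Per-trial MT slope by group (s/trial).
#' @param mt_slope_sd,resid_vmax,resid_fi,resid_mt Noise scales.
#' @param seed Integer seed.
#' @return data.frame with participant, group, WM class and per-trial
#'   metrics; `trial` runs 1..`n_trials`.
#' @export
simulate_metrics_cohort <- function(n_per_group = 23,
                                    n_trials = 180,
                                    vigour_slopes = c(CtrlR = 0.024,
                                                      HaloR = -0.005,
                                                      CtrlNR = 0.013,
                                                      HaloNR = 0.013),
                                    vigour_slope_sd = 0.01,
                                    vigour0_mean = 35, vigour0_sd = 4,
                                    fusion_slopes = c(Ctrl_high = 35e-4,
                                                      Ctrl_low = 20e-4,
                                                      Halo_high = 9e-4,
                                                      Halo_low = 24e-4),
                                    fusion_reward_bonus = 14e-4,
                                    fi0_mean = 1.0, fi0_sd = 0.4,
                                    fi_slope_sd = 1e-3,
                                    mt0_mean = 5.4, mt0_sd = 0.8,
                                    mt_slopes = c(CtrlR = -3.7e-3,
                                                  HaloR = -1.7e-3,
                                                  CtrlNR = -2.7e-3,
                                                  HaloNR = -1.7e-3),
                                    mt_slope_sd = 1.5e-3,
                                    resid_vmax = 5, resid_fi = 0.8,
                                    resid_mt = 0.9,
                                    seed = 1L) {
  groups <- expand.grid(reward_group = c("Rew", "NoRew"),
                        drug_group = c("Halo", "Ctrl"),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (g in seq_len(nrow(groups))) {
      gk <- group_key(groups$reward_group[g], groups$drug_group[g])
      for (k in seq_len(n_per_group)) {
        pid <- pid + 1L
        wm <- if (k %% 2 == 0) "high" else "low" # balanced within cell
        fkey <- paste0(groups$drug_group[g], "_", wm)
        b_v <- vigour_slopes[[gk]] + stats::rnorm(1, 0, vigour_slope_sd)
        b_f <- fusion_slopes[[fkey]] +
          (groups$reward_group[g] == "Rew") * fusion_reward_bonus +
          stats::rnorm(1, 0, fi_slope_sd)
        b_m <- mt_slopes[[gk]] + stats::rnorm(1, 0, mt_slope_sd)
        i_v <- stats::rnorm(1, vigour0_mean, vigour0_sd)
        i_f <- stats::rnorm(1, fi0_mean, fi0_sd)
        i_m <- stats::rnorm(1, mt0_mean, mt0_sd)
        tr <- seq_len(n_trials)
        rows[[pid]] <- data.frame(
          participant_id = sprintf("%s_%02d", gk, k),
          reward_group = groups$reward_group[g],
          drug_group = groups$drug_group[g],
          wm_class = wm, trial = tr,
          vmax_mean = i_v + b_v * tr + stats::rnorm(n_trials, 0, resid_vmax),
          fi_sum = clamp(i_f + b_f * tr +
                           stats::rnorm(n_trials, 0, resid_fi), 0, 7),
          mt = pmax(0.5, i_m + b_m * tr +
                      stats::rnorm(n_trials, 0, resid_mt)))
      }
    }
    do.call(rbind, rows)
  })
}
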