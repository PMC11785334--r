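# Shared fixtures: small configs and noise-free profiles used across tests.

quiet_profile <- function(vigour0 = 21, fusion0 = 0.1, vigour_slope = 0,
                          fusion_slope = 0, noise_sd = 0, id = "p1",
                          reward_group = "Rew", drug_group = "Ctrl") {
  participant_profile(id, reward_group, drug_group,
                      vigour0 = vigour0, vigour_slope = vigour_slope,
                      fusion0 = fusion0, fusion_slope = fusion_slope,
                      noise_sd = noise_sd)
}

# per-group OLS slope of dv on trial (independent oracle for marginal slopes)
ols_group_slopes <- function(tab, dv) {
  sapply(split(tab, group_key_test(tab)), function(d)
    unname(stats::coef(stats::lm(d[[dv]] ~ d$trial))[2]))
}

group_key_test <- function(tab) {
  paste0(tab$drug_group, ifelse(tab$reward_group == "Rew", "R", "NR"))
}

# simple trial table for exclusion tests
toy_trial_table <- function() {
  sched <- build_schedule(1)
  data.frame(participant_id = "p1", day = 1, phase = sched$phase,
             trial = sched$phase_trial, dual_task = sched$dual_task,
             mt = 5)
}
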