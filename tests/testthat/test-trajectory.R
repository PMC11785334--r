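test_that("zero fusion produces a full stop at every transition", {
  cfg <- sim_config()
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0), 1, config = cfg)
  vp <- compute_speed(tr)
  seg <- segment_trial(tr, vp)
  pk <- peak_velocities(vp, seg)
  dt <- 1 / cfg$sampling_rate
  # the stop happens inside the target disc, between the adjacent peaks
  for (k in 1:7) {
    gap <- vp$raw_v[pk$peak_idx[k]:pk$peak_idx[k + 1]]
    expect_gte(sum(gap < 1e-6) * dt, cfg$dwell_floor,
               label = sprintf("stationary dwell at transition %d", k))
  }
})

test_that("high fusion parameter yields high measured fusion indices", {
  tr <- simulate_trajectory(quiet_profile(), 1, trough_fraction = 0.95)
  km <- trial_kinematics(tr)
  expect_true(all(km$fi >= 0.9))
})

test_that("same profile, trial and seed give identical samples", {
  p <- quiet_profile(noise_sd = 0.05)
  a <- simulate_trajectory(p, 3, seed = 77)
  b <- simulate_trajectory(p, 3, seed = 77)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c <- simulate_trajectory(p, 3, seed = 78)
  expect_false(identical(a$x, c$x))
})

test_that("non-positive peak speed is rejected", {
  p <- quiet_profile(vigour0 = 1, vigour_slope = -0.5)
  expect_error(simulate_trajectory(p, 10), "non-positive")
})

test_that("vigour and fusion parameters act on separate metrics", {
  trials <- seq(1, 40, by = 3)
  run <- function(vslope, fslope) {
    p <- quiet_profile(vigour0 = 20, vigour_slope = vslope,
                       fusion0 = 0.2, fusion_slope = fslope)
    km <- lapply(trials, function(i)
      trial_kinematics(simulate_trajectory(p, i)))
    data.frame(trial = trials,
               vmax = vapply(km, `[[`, numeric(1), "vmax_mean"),
               fi = vapply(km, `[[`, numeric(1), "fi_sum"))
  }
  slope <- function(y, x) unname(coef(lm(y ~ x))[2])
  base <- run(0, 0)
  vig <- run(0.06, 0)
  fus <- run(0, 0.004)
  # raising the vigour slope moves the vmax slope, not the FI slope
  expect_gt(slope(vig$vmax, trials) - slope(base$vmax, trials), 0.04)
  expect_lt(abs(slope(vig$fi, trials) - slope(base$fi, trials)), 0.004)
  # raising the fusion slope moves the FI slope, not the vmax slope
  expect_gt(slope(fus$fi, trials) - slope(base$fi, trials), 0.02)
  expect_lt(abs(slope(fus$vmax, trials) - slope(base$vmax, trials)), 0.01)
})

test_that("every generated trajectory segments cleanly, with noise", {
  p <- quiet_profile(noise_sd = 0.03)
  for (i in seq(1, 30, by = 2)) {
    tr <- simulate_trajectory(p, i, seed = 1000 + i,
                              trough_fraction = min(0.9, i * 0.03))
    expect_silent(seg <- segment_trial(tr, compute_speed(tr)))
    expect_equal(nrow(seg), 8)
  }
})

test_that("cohort generation is reproducible and complete", {
  cfg <- sim_config(n_per_group = 1, days = 1, seed = 21)
  co <- simulate_cohort(cfg)
  expect_length(co$profiles, 4)
  counts <- table(co$trials$phase[co$trials$participant_id ==
                                    co$profiles[[1]]$id])
  expect_equal(as.integer(counts[c("Baseline", "Training", "PostRew",
                                   "PostNoRew")]), c(10, 200, 20, 20))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$trials, co2$trials)
})

test_that("growing the cohort preserves existing participants", {
  p <- cohort_profiles(sim_config(n_per_group = 2, seed = 9))
  p_big <- cohort_profiles(sim_config(n_per_group = 3, seed = 9))
  by_id <- function(ps) setNames(ps, vapply(ps, `[[`, character(1), "id"))
  small <- by_id(p)
  big <- by_id(p_big)
  for (id in names(small)) {
    expect_equal(small[[id]]$vigour0, big[[id]]$vigour0, label = id)
    expect_equal(small[[id]]$fusion_slope, big[[id]]$fusion_slope,
                 label = id)
  }
})
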