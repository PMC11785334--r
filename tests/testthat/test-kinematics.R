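make_profile <- function(v, dt = 1 / 110) {
  structure(list(t = seq_along(v) * dt - dt, v = v, raw_v = v, dt = dt),
            class = "velocity_profile")
}

test_that("speed computation recovers constant motion and scales linearly", {
  n <- 111
  t <- (0:(n - 1)) / 110
  tr <- data.frame(t = t, x = 5 * t, y = 0)
  vp <- compute_speed(tr)
  expect_true(all(abs(vp$v[10:100] - 5) < 0.05)) # interior within 1%
  tr2 <- tr
  tr2$x <- tr$x * 2
  vp2 <- compute_speed(tr2)
  expect_equal(vp2$v, vp$v * 2, tolerance = 1e-12)
  # stationary trajectory
  vp0 <- compute_speed(data.frame(t = t, x = 1, y = 2))
  expect_true(all(vp0$v == 0))
})

test_that("non-uniform sampling is rejected, naming the gap", {
  t <- (0:50) / 110
  t[20] <- t[20] + 0.002
  expect_error(compute_speed(data.frame(t = t, x = t, y = 0)),
               "non-uniform sampling")
})

test_that("fusion index follows its defining formula", {
  expect_equal(fusion_index(40, 60, 0), 0)   # full stop
  expect_equal(fusion_index(40, 60, 50), 1)  # trough = mean of peaks
  expect_equal(fusion_index(40, 60, 25), 0.5)
  expect_equal(fusion_index(30, 30, 60), 1)  # clamped from above
  expect_error(fusion_index(0, 60, 10), "positive")
  expect_error(fusion_index(40, 60, -1), "non-negative")
})

test_that("peak velocities take the per-segment maxima", {
  v <- rep(10 * 1:8, each = 10)
  vp <- make_profile(v)
  seg <- data.frame(segment = 1:8, start_idx = seq(1, 71, by = 10),
                    end_idx = seq(10, 80, by = 10))
  pk <- peak_velocities(vp, seg)
  expect_equal(pk$vmax, 10 * 1:8)
  expect_equal(pk$vmax_mean, 45)
  # constant profile: every segment maximum equals the constant
  pkc <- peak_velocities(make_profile(rep(7, 80)), seg)
  expect_equal(pkc$vmax, rep(7, 8))
  expect_error(peak_velocities(vp, data.frame(segment = 1, start_idx = 5,
                                              end_idx = 4)), "empty")
})

test_that("trial fusion decomposes into independent fusion_index calls", {
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0.4), 1)
  vp <- compute_speed(tr)
  seg <- segment_trial(tr, vp)
  pk <- peak_velocities(vp, seg)
  fu <- trial_fusion(vp, seg)
  manual <- vapply(1:7, function(k)
    fusion_index(pk$vmax[k], pk$vmax[k + 1], fu$vmin[k]), numeric(1))
  expect_equal(fu$fi, manual)
  expect_equal(fu$fi_sum, sum(manual))
  expect_lte(fu$fi_sum, 7)
})

test_that("fusion indices are invariant to speed rescaling", {
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0.3), 1)
  vp <- compute_speed(tr)
  seg <- segment_trial(tr, vp)
  fu <- trial_fusion(vp, seg)
  vp2 <- vp
  vp2$v <- vp$v * 3.7
  fu2 <- trial_fusion(vp2, seg)
  pk <- peak_velocities(vp, seg)
  pk2 <- peak_velocities(vp2, seg)
  expect_equal(fu2$fi, fu$fi, tolerance = 1e-12)
  expect_equal(pk2$vmax, pk$vmax * 3.7, tolerance = 1e-12)
})

test_that("segmentation errors identify the first missing target", {
  tr <- simulate_trajectory(quiet_profile(), 1)
  # truncate before target 3 of the sequence (second via visit is index 2)
  lay <- make_target_layout()
  sq <- trial_sequence(lay)
  cr <- seqreach:::target_crossings(tr, lay, sq)
  cut <- tr[seq_len(cr$entry[3] - 5), ]
  class(cut) <- class(tr)
  expect_error(segment_trial(cut, layout = lay, sequence = sq),
               "target 3")
})

test_that("movement time spans start-box exit to final-target entry", {
  cfg <- sim_config()
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0.2), 1, config = cfg)
  mt <- movement_time(tr)
  # manual oracle from the raw samples
  out_box <- which(pmax(abs(tr$x), abs(tr$y)) > 1)[1]
  km <- trial_kinematics(tr)
  expect_equal(mt$mt, km$mt)
  expect_gt(mt$mt, 0)
  expect_gt(mt$reaction_time, 0)
  # time-shifting the trajectory leaves movement time unchanged
  tr_shift <- tr
  tr_shift$t <- tr$t + 1
  expect_equal(movement_time(tr_shift)$mt, mt$mt)
  # truncation before the final target errors
  cut <- tr[1:(out_box + 50), ]
  expect_error(movement_time(cut), "never entered")
})

test_that("movement time decomposes into segment and dwell spans", {
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0), 1)
  vp <- compute_speed(tr)
  seg <- segment_trial(tr, vp)
  km <- trial_kinematics(tr)
  span <- (seg$end_idx[8] - seg$start_idx[1]) * vp$dt
  # mt and the segment span differ only by the start-box/disc offsets
  # (1 cm box edge vs 0.5 cm disc, covered at low speed near the ends)
  expect_lt(abs(km$mt - span), 0.35)
  # segments are ordered and contiguous up to dwell gaps
  expect_true(all(diff(seg$start_idx) > 0))
  expect_true(all(seg$start_idx[-1] >= seg$end_idx[-8]))
})

test_that("trajectory CSV round-trips through the kinematics pipeline", {
  tr <- simulate_trajectory(quiet_profile(fusion0 = 0.3), 1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  km1 <- trial_kinematics(tr)
  km2 <- trial_kinematics(back)
  expect_equal(km2$fi_sum, km1$fi_sum, tolerance = 1e-6)
  expect_equal(km2$mt, km1$mt, tolerance = 1e-9)
})
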