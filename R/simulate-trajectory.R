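# Speed-profile primitives -----------------------------------------------
#
# Each reaching movement is a speed bump along the straight line between two
# target centres: a quintic-smoothstep rise from the entry speed to the peak
# and a symmetric fall to the exit speed. The smoothstep has zero first and
# second derivative at both ends, so the full trial speed profile is C2 with
# flat extrema that survive differentiation and smoothing well.

smoothstep5 <- function(u) u^3 * (10 + u * (-15 + 6 * u))
smoothstep5_int <- function(u) u^4 * (2.5 + u * (-3 + u)) # integral of smoothstep5

# Distance travelled after local time tt within one bump piece.
# a: entry speed, v: peak, b: exit speed, h: half-duration.
bump_distance <- function(tt, a, v, b, h) {
  d <- numeric(length(tt))
  rise <- tt <= h
  u <- tt[rise] / h
  d[rise] <- a * tt[rise] + (v - a) * h * smoothstep5_int(u)
  u2 <- (tt[!rise] - h) / h
  d_half <- h * (a + v) / 2
  d[!rise] <- d_half + v * (tt[!rise] - h) - (v - b) * h * smoothstep5_int(u2)
  d
}

bump_duration <- function(L, a, v, b) 4 * L / (a + b + 2 * v)

# Build the sampled noise-free path for a given vector of junction speeds.
# Segment durations are rounded to even multiples of the sampling interval
# (peak speeds re-solved accordingly) so every direction reversal at a
# target and every speed peak falls exactly on a sample instant: speed
# estimated by first differences is then never attenuated by a sampling
# interval straddling a turn.
build_reach_path <- function(junc, v_peak, pts, lens, config) {
  n_seg <- length(lens)
  dt <- 1 / config$sampling_rate
  peaks <- rep(v_peak, n_seg)
  entry <- c(0, junc)
  exit <- c(junc, 0)
  for (it in 1:3) {
    durs_seg <- vapply(seq_len(n_seg), function(k)
      bump_duration(lens[k], entry[k], peaks[k], exit[k]), numeric(1))
    durs_seg <- 2 * dt * pmax(2, round(durs_seg / (2 * dt)))
    peaks <- (4 * lens / durs_seg - entry - exit) / 2
    if (any(peaks <= 0))
      stop("non-positive segment peak speed after duration rounding; ",
           "increase vigour")
  }

  snap <- function(x) dt * max(1, round(x / dt))
  pieces <- list(list(type = "hold", dur = snap(config$reaction_time),
                      p0 = pts[1, ], p1 = pts[1, ]))
  for (k in seq_len(n_seg)) {
    pieces[[length(pieces) + 1]] <-
      list(type = "bump", dur = durs_seg[k], a = entry[k], v = peaks[k],
           b = exit[k], L = lens[k], p0 = pts[k, ], p1 = pts[k + 1, ])
    if (k < n_seg && junc[k] <= 1e-12)
      pieces[[length(pieces) + 1]] <-
        list(type = "hold", dur = dt * ceiling(config$dwell_floor / dt),
             p0 = pts[k + 1, ], p1 = pts[k + 1, ])
  }
  pieces[[length(pieces) + 1]] <- list(type = "hold",
                                       dur = snap(config$tail_time),
                                       p0 = pts[nrow(pts), ],
                                       p1 = pts[nrow(pts), ])

  durs <- vapply(pieces, `[[`, numeric(1), "dur")
  starts <- cumsum(c(0, durs[-length(durs)]))
  t <- dt * seq(0, round(sum(durs) / dt))
  idx <- findInterval(t + dt / 4, starts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L

  xy <- matrix(NA_real_, length(t), 2)
  for (j in seq_along(pieces)) {
    sel <- idx == j
    if (!any(sel)) next
    pc <- pieces[[j]]
    if (pc$type == "hold") {
      xy[sel, 1] <- pc$p0[1]
      xy[sel, 2] <- pc$p0[2]
    } else {
      tt <- t[sel] - starts[j]
      d <- clamp(bump_distance(tt, pc$a, pc$v, pc$b, durs[j] / 2), 0, pc$L)
      w <- d / pc$L
      xy[sel, 1] <- pc$p0[1] + w * (pc$p1[1] - pc$p0[1])
      xy[sel, 2] <- pc$p0[2] + w * (pc$p1[2] - pc$p0[2])
    }
  }
  list(t = t, xy = xy, peaks = peaks,
       seg_durations = durs_seg)
}

# Fully fused reference path: constant cruise speed along the whole target
# polyline (quintic ramps from/to rest at the ends). The cruise speed is
# taken from the family v = 5 cm / (m * dt) so that every target vertex
# falls exactly on a sample instant: the measured smoothed speed is then
# constant across all transitions and every fusion index is exactly 1.
build_fused_path <- function(v_nom, pts, lens, config) {
  dt <- 1 / config$sampling_rate
  unit <- 5 # gcd of the segment lengths (cm)
  stopifnot(all(abs(lens / unit - round(lens / unit)) < 1e-9))
  m <- max(2, round(unit / (v_nom * dt)))
  v <- unit / (m * dt)
  h <- 2 * dt * max(2, round(1.5 / (v * dt) / 2)) # ramp duration, even grid
  D <- sum(lens)
  cruise <- (D - h * v) / v # cruise time; h*v/2 covered in each ramp
  stopifnot(cruise > 0)
  snap <- function(x) dt * max(1, round(x / dt))
  t_rt <- snap(config$reaction_time)
  t_tail <- snap(config$tail_time)
  total <- t_rt + h + cruise + h + t_tail
  t <- dt * seq(0, round(total / dt))
  tm <- t - t_rt # time since movement onset
  s <- numeric(length(t))
  ramp1 <- tm > 0 & tm <= h
  s[ramp1] <- v * h * smoothstep5_int(tm[ramp1] / h)
  mid <- tm > h & tm <= h + cruise
  s[mid] <- v * h / 2 + v * (tm[mid] - h)
  u <- tm - h - cruise
  down <- u > 0 & u <= h
  s[down] <- D - v * h / 2 + v * u[down] - v * h * smoothstep5_int(u[down] / h)
  s[u > h] <- D
  s <- clamp(s, 0, D)
  cumL <- c(0, cumsum(lens))
  seg <- pmin(pmax(findInterval(s, cumL, rightmost.closed = TRUE), 1),
              length(lens))
  w <- (s - cumL[seg]) / lens[seg]
  xy <- cbind(pts[seg, 1] + w * (pts[seg + 1, 1] - pts[seg, 1]),
              pts[seg, 2] + w * (pts[seg + 1, 2] - pts[seg, 2]))
  list(t = t, xy = xy, peaks = rep(v, length(lens)),
       seg_durations = lens / v + c(h / 2, rep(0, length(lens) - 2), h / 2))
}

# Measured per-transition speed ratio (trough over mean adjacent smoothed
# peak) of a noise-free path, using the same measurement the kinematics
# module applies.
measure_trough_ratio <- function(path, layout, sequence) {
  traj <- data.frame(t = path$t, x = path$xy[, 1], y = path$xy[, 2])
  vp <- compute_speed(traj)
  seg <- segment_trial(traj, vp, layout, sequence)
  pk <- peak_velocities(vp, seg)
  fu <- trial_fusion(vp, seg)
  fu$vmin / ((pk$vmax[-length(pk$vmax)] + pk$vmax[-1]) / 2)
}

# Trajectory generator ----------------------------------------------------

#' Simulate one sequential reaching trial
#'
#' Generates the 2-D cursor path of a single trial: eight reaching movements
#' through the target sequence (out-and-back to each outer target through the
#' via point), sampled at the tracker rate. Per-segment peak speed is
#' `vigour0 + vigour_slope * trial_index` (all segments share the trial's
#' nominal peak speed) and the speed trough at each of the 7 inter-movement
#' transitions is programmed as `trough_fraction` of the mean adjacent
#' segment peak. Because the analysis measures fusion on the
#' Gaussian-smoothed, finite-difference speed profile, the junction speeds
#' are calibrated by a short fixed-point iteration against that measurement
#' on the noise-free path, so the programmed fraction is the one the
#' kinematics module recovers. A trough fraction of 0 produces a full stop
#' with a stationary dwell of at least `config$dwell_floor` seconds; a
#' fraction of 1 produces a fully fused trial whose measured speed never
#' drops between movements. Additive Gaussian positional noise with sd
#' `profile$noise_sd` is applied to every sample.
#'
#' @param profile A [participant_profile()].
#' @param trial_index Trial number (>= 1) driving the learning slopes.
#' @param layout A [make_target_layout()] layout.
#' @param config A [sim_config()].
#' @param seed Optional integer; if given, the trial is a pure function of it.
#' @param trough_fraction Optional override in [0, 1] for the transition
#'   trough fraction (bypasses the profile's fusion parameters and the
#'   `config$fusion_cap` clamp; used for reference trials).
#' @param phase,day,dual_task Metadata attached to the trajectory.
#' @return A data.frame of class `trajectory` with columns `t`, `x`, `y`
#'   (seconds / cm) and metadata attributes (`participant_id`, `trial_id`,
#'   `phase`, `day`, `dual_task`, `meta`).
#' @export
simulate_trajectory <- function(profile, trial_index,
                                layout = make_target_layout(),
                                config = sim_config(), seed = NULL,
                                trough_fraction = NULL,
                                phase = "Training", day = 1L,
                                dual_task = FALSE) {
  stopifnot(trial_index >= 1)
  v_peak <- profile$vigour0 + profile$vigour_slope * trial_index
  if (!is.finite(v_peak) || v_peak <= 0)
    stop("non-positive segment peak speed (", signif(v_peak, 3),
         " cm/s) for trial_index ", trial_index)
  f <- if (!is.null(trough_fraction)) {
    stopifnot(trough_fraction >= 0, trough_fraction <= 1)
    trough_fraction
  } else {
    clamp(profile$fusion0 + profile$fusion_slope * trial_index,
          0, config$fusion_cap)
  }

  seq_pts <- trial_sequence(layout, config$outer_order)
  pts <- rbind(via = layout$via, seq_pts) # 9 waypoints, 8 movements
  lens <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  n_seg <- length(lens)

  if (f >= 0.995) {
    path <- build_fused_path(v_peak, pts, lens, config)
    junc <- rep(path$peaks[1], n_seg - 1)
  } else {
    junc <- rep(f * v_peak, n_seg - 1)
    path <- build_reach_path(junc, v_peak, pts, lens, config)
    if (f > 0) {
      for (it in 1:6) {
        ratio <- measure_trough_ratio(path, layout, seq_pts)
        if (max(abs(ratio - f)) < 0.002) break
        junc <- clamp(junc * f / pmax(ratio, 1e-3), 0, v_peak)
        path <- build_reach_path(junc, v_peak, pts, lens, config)
      }
    }
  }

  xy <- path$xy
  if (profile$noise_sd > 0) {
    xy <- with_seed(seed, xy + matrix(stats::rnorm(2 * length(path$t), 0,
                                                   profile$noise_sd),
                                      ncol = 2))
  }

  out <- data.frame(t = path$t, x = xy[, 1], y = xy[, 2])
  attr(out, "participant_id") <- profile$id
  attr(out, "trial_id") <- trial_index
  attr(out, "phase") <- phase
  attr(out, "day") <- day
  attr(out, "dual_task") <- dual_task
  attr(out, "meta") <- list(peak_speed = v_peak,
                            realised_peaks = path$peaks,
                            trough_fraction = f,
                            junction_speeds = junc,
                            segment_durations = path$seg_durations,
                            sequence = rownames(seq_pts))
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(
    "trajectory: participant %s, trial %s (%s, day %s)%s\n",
    attr(x, "participant_id"), attr(x, "trial_id"), attr(x, "phase"),
    attr(x, "day"), if (isTRUE(attr(x, "dual_task"))) " [dual task]" else ""))
  cat(sprintf("  %d samples over %.2f s; peak speed %.1f cm/s, trough fraction %.2f\n",
              nrow(x), max(x$t), m$peak_speed, m$trough_fraction))
  invisible(x)
}
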