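# Kinematic measurement: speed profiles, segmentation, peak velocity,
# fusion index and movement time for one trial.

#' Speed profile of a trajectory
#'
#' Differentiates the positional data by first differences and smooths the
#' resulting speed with a Gaussian kernel (default sigma = 2 samples,
#' truncated at +/- 4 sigma, reflective boundaries). Speed sample i is the
#' Euclidean displacement from sample i to i+1 divided by the time step, so
#' the profile has one sample fewer than the trajectory.
#'
#' @param trajectory A `trajectory` (or any data.frame with `t`, `x`, `y`).
#' @param sigma Gaussian smoothing width in samples.
#' @param dt_tol Tolerance (s) for non-uniform sampling.
#' @return A list of class `velocity_profile`: `t` (time of each speed
#'   sample), `v` (smoothed speed, cm/s), `raw_v` (unsmoothed), `dt`.
#' @export
compute_speed <- function(trajectory, sigma = 2, dt_tol = 1e-9) {
  t <- trajectory$t
  n <- length(t)
  if (n < 3) stop("need at least 3 samples to compute a speed profile")
  dts <- diff(t)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > dt_tol)
  if (length(bad))
    stop(sprintf(
      "non-uniform sampling: gap of %.9g s between samples %d and %d (expected %.9g s)",
      dts[bad[1]], bad[1], bad[1] + 1, dt))
  raw_v <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2) / dt
  v <- gauss_smooth(raw_v, sigma)
  structure(list(t = t[-n], v = pmax(v, 0), raw_v = raw_v, dt = dt),
            class = "velocity_profile")
}

# Gaussian smoothing, kernel truncated at +/- 4 sigma, reflective boundaries.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  if (n <= half + 1) stop("signal too short for smoothing window")
  pad <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("velocity profile: %d samples at %.1f Hz, peak %.1f cm/s\n",
              length(x$v), 1 / x$dt, max(x$v)))
  invisible(x)
}

# Entry/exit bookkeeping: first entries into and exits from each disc of the
# visit sequence, scanned monotonically so repeated via visits resolve in
# order. Point-cursor convention: the cursor centre crossing the 0.5 cm
# target radius defines entry/exit.
target_crossings <- function(trajectory, layout,
                             sequence = trial_sequence(layout)) {
  r <- layout$target_diameter / 2
  pos <- cbind(trajectory$x, trajectory$y)
  n <- nrow(pos)
  m <- nrow(sequence)
  entry <- exit <- integer(m)
  # segment 1 starts when the cursor leaves the via disc it starts in
  d0 <- sqrt((pos[, 1] - layout$via[1])^2 + (pos[, 2] - layout$via[2])^2)
  start_exit <- which(d0 > r)[1]
  if (is.na(start_exit)) stop("cursor never left the via target")
  cursor <- start_exit
  for (k in seq_len(m)) {
    dk <- sqrt((pos[, 1] - sequence[k, 1])^2 + (pos[, 2] - sequence[k, 2])^2)
    ent <- which(dk[cursor:n] <= r)[1]
    if (is.na(ent))
      stop(sprintf("target %d (%s) never entered (in order)", k,
                   rownames(sequence)[k]))
    entry[k] <- cursor + ent - 1L
    ex <- which(dk[entry[k]:n] > r)[1]
    exit[k] <- if (is.na(ex)) NA_integer_ else entry[k] + ex - 1L
    if (k < m && is.na(exit[k]))
      stop(sprintf("target %d (%s) entered but never exited", k,
                   rownames(sequence)[k]))
    cursor <- if (is.na(exit[k])) entry[k] else exit[k]
  }
  list(entry = entry, exit = exit, start_exit = start_exit)
}

#' Segment a trial into its 8 reaching movements
#'
#' Segment k spans from the sample where the cursor exits target k-1's disc
#' (the start position's via disc for k = 1) to the sample where it exits
#' target k's disc; the final segment ends at the first entry into the final
#' target. Targets must be hit in sequence order.
#'
#' @param trajectory A `trajectory`.
#' @param profile Optional `velocity_profile` (used only to clip bounds to
#'   the speed-sample range).
#' @param layout A `target_layout`.
#' @param sequence Ordered target centres, as from [trial_sequence()].
#' @return data.frame of class `segment_bounds`: `segment`, `start_idx`,
#'   `end_idx` (indices into the speed profile).
#' @export
segment_trial <- function(trajectory, profile = NULL,
                          layout = make_target_layout(),
                          sequence = trial_sequence(layout)) {
  cr <- target_crossings(trajectory, layout, sequence)
  m <- nrow(sequence)
  starts <- c(cr$start_exit, cr$exit[-m])
  ends <- c(cr$exit[-m], cr$entry[m])
  nmax <- nrow(trajectory) - 1L # speed profile length
  if (!is.null(profile)) nmax <- length(profile$v)
  out <- data.frame(segment = seq_len(m),
                    start_idx = pmin(starts, nmax),
                    end_idx = pmin(ends, nmax))
  class(out) <- c("segment_bounds", "data.frame")
  out
}

#' Per-segment peak velocities
#'
#' Maximum of the smoothed speed within each segment, and their mean over
#' the trial.
#'
#' @param profile A `velocity_profile`.
#' @param segments A `segment_bounds` data.frame.
#' @return List with `vmax` (named vector, cm/s), `vmax_mean`, and
#'   `peak_idx` (speed-sample index of each maximum).
#' @export
peak_velocities <- function(profile, segments) {
  vmax <- numeric(nrow(segments))
  peak_idx <- integer(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    i0 <- segments$start_idx[k]
    i1 <- segments$end_idx[k]
    if (i1 < i0) stop("empty segment ", k)
    w <- profile$v[i0:i1]
    vmax[k] <- max(w)
    peak_idx[k] <- i0 + which.max(w) - 1L
  }
  list(vmax = vmax, vmax_mean = mean(vmax), peak_idx = peak_idx)
}

#' Fusion index of one movement transition
#'
#' Movement fusion quantifies coarticulation of two sequential reaches: the
#' closer the speed trough between them to the mean of the two segment peak
#' speeds, the more the movements are blended. The index is
#' `1 - (mean(vmax1, vmax2) - vmin) / mean(vmax1, vmax2)`, i.e. the trough
#' as a fraction of the mean adjacent peak; 0 marks a complete stop and 1 a
#' fully fused transition. Values are clamped to [0, 1] (a trough can
#' numerically exceed the mean of the peaks).
#'
#' @param vmax1,vmax2 Peak speeds of the two adjacent segments (cm/s, > 0).
#' @param vmin Minimum speed between the two peaks (cm/s, >= 0).
#' @return Fusion index in [0, 1]; vectorised over its arguments.
#' @examples
#' fusion_index(40, 60, 50) # trough equals mean of peaks: fully fused, 1
#' fusion_index(40, 60, 25) # 0.5
#' @export
fusion_index <- function(vmax1, vmax2, vmin) {
  if (any(vmax1 <= 0) || any(vmax2 <= 0))
    stop("segment peak speeds must be positive")
  if (any(vmin < 0)) stop("trough speed must be non-negative")
  m <- (vmax1 + vmax2) / 2
  clamp(1 - (m - vmin) / m, 0, 1)
}

#' Per-transition fusion indices of a trial
#'
#' For each of the 7 transitions between the 8 segments, finds the minimum
#' smoothed speed between the two adjacent segments' peak-speed samples and
#' converts it to a fusion index via [fusion_index()].
#'
#' @param profile A `velocity_profile`.
#' @param segments A `segment_bounds` data.frame (8 segments).
#' @return List with `fi` (7 indices), `fi_sum`, `vmin` (7 trough speeds),
#'   `n_clamped` (count of raw indices outside [0, 1]).
#' @export
trial_fusion <- function(profile, segments) {
  pk <- peak_velocities(profile, segments)
  n <- length(pk$vmax)
  fi <- vmin <- numeric(n - 1)
  n_clamped <- 0L
  for (k in seq_len(n - 1)) {
    i0 <- pk$peak_idx[k]
    i1 <- pk$peak_idx[k + 1]
    win <- if (i1 - i0 >= 2) (i0 + 1):(i1 - 1) else i0:i1 # open interval
    vmin[k] <- min(profile$v[win])
    m <- (pk$vmax[k] + pk$vmax[k + 1]) / 2
    raw <- 1 - (m - vmin[k]) / m
    if (raw < 0 || raw > 1) n_clamped <- n_clamped + 1L
    fi[k] <- fusion_index(pk$vmax[k], pk$vmax[k + 1], vmin[k])
  }
  list(fi = fi, fi_sum = sum(fi), vmin = vmin, n_clamped = n_clamped)
}

#' Movement time and reaction time of a trial
#'
#' Movement time is the time between exiting the 2 x 2 cm start box (centred
#' on the via target) and first entering the final target; it includes
#' reaction time, reported separately as the time from the go signal (first
#' sample) until displacement from the start position exceeds 2 cm.
#'
#' @param trajectory A `trajectory`.
#' @param layout A `target_layout`.
#' @param sequence Ordered target centres.
#' @return List with `mt` and `reaction_time` (s).
#' @export
movement_time <- function(trajectory, layout = make_target_layout(),
                          sequence = trial_sequence(layout)) {
  half <- layout$start_box_side / 2
  out_box <- which(pmax(abs(trajectory$x - layout$via[1]),
                        abs(trajectory$y - layout$via[2])) > half)[1]
  if (is.na(out_box)) stop("cursor never left the start box")
  cr <- target_crossings(trajectory, layout, sequence)
  t_end <- trajectory$t[cr$entry[nrow(sequence)]]
  x0 <- trajectory$x[1]
  y0 <- trajectory$y[1]
  moved <- which(sqrt((trajectory$x - x0)^2 + (trajectory$y - y0)^2) > 2)[1]
  list(mt = t_end - trajectory$t[out_box],
       reaction_time = if (is.na(moved)) NA_real_
                       else trajectory$t[moved] - trajectory$t[1])
}

#' All kinematic metrics for one trial
#'
#' Convenience wrapper running [compute_speed()], [segment_trial()],
#' [peak_velocities()], [trial_fusion()] and [movement_time()].
#'
#' @inheritParams compute_speed
#' @inheritParams segment_trial
#' @return A list of class `trial_kinematics`: `mt`, `reaction_time`,
#'   `vmax` (8), `vmax_mean`, `fi` (7), `fi_sum`, `vmin` (7), `n_clamped`.
#' @export
trial_kinematics <- function(trajectory, layout = make_target_layout(),
                             sequence = trial_sequence(layout), sigma = 2) {
  vp <- compute_speed(trajectory, sigma = sigma)
  seg <- segment_trial(trajectory, vp, layout, sequence)
  pk <- peak_velocities(vp, seg)
  fu <- trial_fusion(vp, seg)
  mt <- movement_time(trajectory, layout, sequence)
  structure(list(mt = mt$mt, reaction_time = mt$reaction_time,
                 vmax = pk$vmax, vmax_mean = pk$vmax_mean,
                 fi = fu$fi, fi_sum = fu$fi_sum, vmin = fu$vmin,
                 n_clamped = fu$n_clamped),
            class = "trial_kinematics")
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf("trial kinematics: MT %.2f s (RT %.2f s), mean vmax %.1f cm/s, FI sum %.2f\n",
              x$mt, x$reaction_time, x$vmax_mean, x$fi_sum))
  invisible(x)
}
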