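#' Kinematic extraction configuration
#'
#' Tuning parameters for trajectory preprocessing and movement-parameter
#' extraction. Defaults follow the standard whole-body AAT preprocessing
#' recipe: an order-2 Savitzky-Golay filter over 11 samples, a 10 cm/s speed
#' cutoff separating steps from postural sway, a 0.10 m/s onset threshold on
#' the smoothed speed curve, and a 10 cm opposite-direction excursion rule
#' for incorrect trials. `sustain_samples` requires the onset crossing to
#' persist (3 samples at 85 Hz is about 35 ms), rejecting isolated noise
#' spikes.
#'
#' @param sg_window Savitzky-Golay window length, samples (odd).
#' @param sg_order Savitzky-Golay polynomial degree.
#' @param sway_cutoff Speed below which motion counts as sway, m/s.
#' @param onset_threshold Speed that must be exceeded to call a movement
#'   onset, m/s.
#' @param opposite_direction_limit Displacement against the instructed
#'   direction that classifies a trial incorrect, m.
#' @param sustain_samples Consecutive supra-threshold samples required at
#'   onset.
#' @param resample_rate Target uniform sampling rate, Hz.
#' @return A list of class `kinematic_config`.
#' @export
kinematic_config <- function(sg_window = 11, sg_order = 2,
                             sway_cutoff = 0.10, onset_threshold = 0.10,
                             opposite_direction_limit = 0.10,
                             sustain_samples = 3, resample_rate = 85) {
  if (sg_window %% 2 != 1 || sg_window <= sg_order) {
    aat_abort("sg_window must be odd and greater than sg_order", "bad_config")
  }
  if (any(c(sway_cutoff, onset_threshold, opposite_direction_limit,
            resample_rate) <= 0) || sustain_samples < 1) {
    aat_abort("thresholds must be positive", "bad_config")
  }
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 sway_cutoff = sway_cutoff,
                 onset_threshold = onset_threshold,
                 opposite_direction_limit = opposite_direction_limit,
                 sustain_samples = as.integer(sustain_samples),
                 resample_rate = resample_rate),
            class = "kinematic_config")
}

#' Resample a trajectory onto a uniform time grid
#'
#' Linearly interpolates each coordinate onto an evenly spaced grid spanning
#' the original time range. Tracker logs are only approximately regular;
#' the smoothing filter assumes equal spacing.
#'
#' @param samples Data frame with columns `t`, `x`, `y`, `z`.
#' @param rate Target rate, Hz.
#' @return Tibble with the same columns on the uniform grid.
#' @export
resample_uniform <- function(samples, rate = 85) {
  if (nrow(samples) < 2) aat_abort("need at least 2 samples", "bad_trajectory")
  if (anyDuplicated(samples$t)) {
    aat_abort("duplicate timestamps in trajectory", "bad_trajectory")
  }
  if (is.unsorted(samples$t, strictly = TRUE)) {
    aat_abort("timestamps must be strictly increasing", "bad_trajectory")
  }
  grid <- seq(samples$t[1], samples$t[nrow(samples)], by = 1 / rate)
  tibble(t = grid,
         x = approx(samples$t, samples$x, grid)$y,
         y = approx(samples$t, samples$y, grid)$y,
         z = approx(samples$t, samples$z, grid)$y)
}

# Savitzky-Golay smooth of one series; interior via the centre row of the
# projection matrix, edges via shrinking symmetric windows (a window of
# 2m+1 points around point i, m = min(i-1, n-i, half), refit at each edge
# point; windows of <= order+1 points reproduce the data).
sg_smooth_series <- function(v, window, order) {
  n <- length(v)
  if (n < window) {
    aat_abort(sprintf("series of length %d is shorter than sg_window = %d",
                      n, window), "too_short")
  }
  half <- (window - 1L) %/% 2L
  coefs <- signal::sgolay(p = order, n = window)[half + 1L, ]
  out <- stats::filter(v, coefs, sides = 2)
  out <- as.numeric(out)
  for (i in seq_len(half)) {
    for (idx in c(i, n - i + 1L)) {
      m <- i - 1L
      if (m == 0L || 2L * m + 1L <= order + 1L) {
        out[idx] <- v[idx]
      } else {
        w <- (idx - m):(idx + m)
        deg <- min(order, 2L * m)
        fit <- stats::lm.fit(outer(seq(-m, m), 0:deg, `^`), v[w])
        out[idx] <- fit$coefficients[1]
      }
    }
  }
  out
}

#' Smooth a trajectory with a Savitzky-Golay filter
#'
#' Replaces each coordinate by its local least-squares polynomial fit of
#' degree `sg_order` over a centred window of `sg_window` samples. At the
#' series edges the window shrinks symmetrically (edge points whose maximal
#' symmetric window has no more points than the polynomial has coefficients
#' are returned unchanged).
#'
#' @param samples Data frame with `t`, `x`, `y`, `z` on a uniform grid.
#' @param config A [kinematic_config()].
#' @return Tibble with smoothed `x`, `y`, `z`.
#' @export
smooth_trajectory <- function(samples, config = kinematic_config()) {
  tibble(t = samples$t,
         x = sg_smooth_series(samples$x, config$sg_window, config$sg_order),
         y = sg_smooth_series(samples$y, config$sg_window, config$sg_order),
         z = sg_smooth_series(samples$z, config$sg_window, config$sg_order))
}

#' Per-sample horizontal movement speed
#'
#' Magnitude of the derivative of the horizontal (x, z) position, by central
#' differences on the interior and one-sided differences at the endpoints.
#' Vertical head bob is ignored: whole-body steps are horizontal.
#'
#' @param samples Data frame with `t`, `x`, `z` on a uniform grid.
#' @return Numeric vector of speeds, m/s, one per sample.
#' @export
compute_speed <- function(samples) {
  t <- samples$t; n <- length(t)
  if (n < 2) aat_abort("need at least 2 samples", "bad_trajectory")
  d1 <- function(v) {
    g <- numeric(n)
    g[1] <- (v[2] - v[1]) / (t[2] - t[1])
    g[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      g[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
    }
    g
  }
  sqrt(d1(samples$x)^2 + d1(samples$z)^2)
}

#' Detect movement onset from a speed series
#'
#' Returns the time of the first sample after `stimulus_onset` at which the
#' speed exceeds `onset_threshold` and stays above it for `sustain_samples`
#' consecutive samples, or `NA` if no such crossing exists (a missing trial,
#' not an error).
#'
#' @param speed Speeds, m/s (aligned with `t`).
#' @param t Sample times, s.
#' @param stimulus_onset Time from which to search, s.
#' @param config A [kinematic_config()].
#' @return List with `onset` (s, or `NA`) and `rt_ms` (onset minus
#'   `stimulus_onset` in ms, or `NA`).
#' @export
detect_onset <- function(speed, t, stimulus_onset = 0,
                         config = kinematic_config()) {
  k <- config$sustain_samples
  eligible <- t >= stimulus_onset
  above <- speed > config$onset_threshold & eligible
  run <- stats::filter(as.numeric(above), rep(1, k), sides = 1)
  hit <- which(run == k)
  if (length(hit) == 0) return(list(onset = NA_real_, rt_ms = NA_real_))
  i <- hit[1] - k + 1L
  list(onset = t[i], rt_ms = (t[i] - stimulus_onset) * 1000)
}

# projection of horizontal displacement onto the subject->avatar unit axis
project_axis <- function(dx, dz, axis) dx * axis[1] + dz * axis[2]

subject_avatar_axis <- function(start_x, start_z, avatar_x, avatar_z) {
  v <- c(avatar_x - start_x, avatar_z - start_z)
  v / sqrt(sum(v^2))
}

#' Extract movement parameters after a detected onset
#'
#' The movement segment runs from the onset to the first sample after the
#' speed maximum at which speed falls below `sway_cutoff` (or to `end_limit`,
#' typically the rating onset, if it never does). Peak velocity is the
#' maximum speed in the segment; step size is the absolute displacement from
#' the onset position to the segment-end position projected on the
#' subject-to-avatar horizontal axis, in cm.
#'
#' @param samples Smoothed trajectory (`t`, `x`, `z`).
#' @param speed Speeds from [compute_speed()].
#' @param onset Onset time from [detect_onset()], s.
#' @param axis Unit vector (x, z) pointing from subject start to avatar.
#' @param config A [kinematic_config()].
#' @param end_limit Last admissible time, s (default last sample).
#' @return List with `peak_velocity` (m/s), `step_size` (cm),
#'   `move_start`, `move_end` (s).
#' @export
extract_movement <- function(samples, speed, onset, axis,
                             config = kinematic_config(),
                             end_limit = NULL) {
  if (is.na(onset)) aat_abort("onset is missing", "no_onset")
  end_limit <- end_limit %||% samples$t[nrow(samples)]
  win <- which(samples$t >= onset & samples$t <= end_limit)
  pk <- win[which.max(speed[win])]
  after <- win[win > pk]
  below <- after[speed[after] < config$sway_cutoff]
  endi <- if (length(below) > 0) below[1] else win[length(win)]
  starti <- win[1]
  disp <- project_axis(samples$x[endi] - samples$x[starti],
                       samples$z[endi] - samples$z[starti], axis)
  list(peak_velocity = max(speed[win[win <= endi]]),
       step_size = abs(disp) * 100,
       move_start = samples$t[starti], move_end = samples$t[endi])
}

#' Classify trial direction
#'
#' A trial is `missing` when no movement onset occurred before the response
#' marker, `incorrect` when the signed displacement from the stimulus-onset
#' position ever reaches `opposite_direction_limit` (10 cm) against the
#' instructed direction, and `correct` otherwise. Displacement is projected
#' on the subject-to-avatar axis with approach positive.
#'
#' @param samples Smoothed trajectory.
#' @param instructed `"approach"` or `"avoidance"`.
#' @param onset Onset time (s) or `NA`.
#' @param axis Unit (x, z) vector toward the avatar.
#' @param stimulus_onset Stimulus onset time, s.
#' @param response_onset Rating-onset marker, s.
#' @param config A [kinematic_config()].
#' @return `"correct"`, `"incorrect"` or `"missing"`.
#' @export
classify_direction <- function(samples, instructed, onset, axis,
                               stimulus_onset = 0, response_onset = Inf,
                               config = kinematic_config()) {
  if (!instructed %in% c("approach", "avoidance")) {
    aat_abort(paste0("unknown instructed direction: ", instructed),
              "bad_direction")
  }
  if (is.na(onset) || onset > response_onset) return("missing")
  i0 <- which(samples$t >= stimulus_onset)[1]
  win <- which(samples$t >= stimulus_onset & samples$t <= response_onset)
  disp <- project_axis(samples$x[win] - samples$x[i0],
                       samples$z[win] - samples$z[i0], axis)
  sign <- if (instructed == "approach") 1 else -1
  if (any(sign * disp <= -config$opposite_direction_limit)) "incorrect"
  else "correct"
}

#' Interpersonal distance and approach peak velocity
#'
#' IPD is the horizontal Euclidean distance between the head position at the
#' confirm-press marker (linearly interpolated between samples) and the
#' avatar position, in cm. Peak velocity is the maximum horizontal speed
#' between stimulus onset and the confirm press. Trials in which the speed
#' never exceeds the onset threshold before the confirm press (no forward
#' movement) are flagged missing.
#'
#' @param samples Smoothed trajectory.
#' @param speed Speeds from [compute_speed()].
#' @param confirm_press Confirm-press time, s.
#' @param avatar_pos Avatar horizontal position `c(x, z)`, m.
#' @param stimulus_onset Stimulus onset, s.
#' @param config A [kinematic_config()].
#' @return List with `ipd` (cm), `peak_velocity` (m/s), `missing` (logical).
#' @export
compute_ipd <- function(samples, speed, confirm_press, avatar_pos,
                        stimulus_onset = 0, config = kinematic_config()) {
  if (is.null(confirm_press) || is.na(confirm_press)) {
    aat_abort("confirm-press marker absent", "no_marker")
  }
  tc <- min(confirm_press, samples$t[nrow(samples)])
  hx <- approx(samples$t, samples$x, tc)$y
  hz <- approx(samples$t, samples$z, tc)$y
  ipd <- sqrt((hx - avatar_pos[1])^2 + (hz - avatar_pos[2])^2) * 100
  win <- which(samples$t >= stimulus_onset & samples$t <= confirm_press)
  pv <- max(speed[win])
  list(ipd = ipd, peak_velocity = pv,
       missing = pv <= config$onset_threshold)
}

#' Extract kinematic parameters for every trial
#'
#' Data-frame-first driver over all trials: resamples each trajectory to a
#' uniform grid, smooths it, computes the speed curve, and extracts the
#' per-trial dependent variables. AAT trials yield initiation RT, peak
#' velocity, step size and a direction classification; IPD trials yield the
#' stopping distance and peak velocity.
#'
#' @param trials Trial metadata tibble (see [simulate_cohort()]): must have
#'   `trial_id`, `experiment`, `direction`, `stimulus_onset`,
#'   `response_onset`, `avatar_x`, `avatar_z`.
#' @param samples Trajectory tibble `trial_id`, `t`, `x`, `y`, `z`.
#' @param config A [kinematic_config()].
#' @return The `trials` tibble with extraction columns appended: `rt_ms`,
#'   `peak_velocity`, `step_size`, `direction_class`, `move_start`,
#'   `move_end`, `ipd`.
#' @export
extract_kinematics <- function(trials, samples,
                               config = kinematic_config()) {
  traj_list <- split(samples[, c("t", "x", "y", "z")],
                     factor(samples$trial_id, levels = trials$trial_id))
  n <- nrow(trials)
  rt <- pv <- ss <- ms <- me <- ipd <- rep(NA_real_, n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    traj <- traj_list[[tr$trial_id]]
    if (is.null(traj) || nrow(traj) < config$sg_window) {
      cls[i] <- "missing"
      next
    }
    traj <- resample_uniform(traj, config$resample_rate)
    sm <- smooth_trajectory(traj, config)
    spd <- compute_speed(sm)
    axis <- subject_avatar_axis(sm$x[1], sm$z[1], tr$avatar_x, tr$avatar_z)
    if (tr$experiment == "AAT") {
      det <- detect_onset(spd, sm$t, tr$stimulus_onset, config)
      cls[i] <- classify_direction(sm, tr$direction, det$onset, axis,
                                   tr$stimulus_onset, tr$response_onset,
                                   config)
      if (cls[i] != "missing") {
        mv <- extract_movement(sm, spd, det$onset, axis, config,
                               end_limit = tr$response_onset)
        rt[i] <- det$rt_ms; pv[i] <- mv$peak_velocity
        ss[i] <- mv$step_size; ms[i] <- mv$move_start; me[i] <- mv$move_end
      }
    } else {
      res <- compute_ipd(sm, spd, tr$response_onset,
                         c(tr$avatar_x, tr$avatar_z),
                         tr$stimulus_onset, config)
      if (res$missing) {
        cls[i] <- "missing"
      } else {
        cls[i] <- "correct"
        ipd[i] <- res$ipd; pv[i] <- res$peak_velocity
      }
    }
  }
  trials |>
    mutate(rt_ms = rt, peak_velocity = pv, step_size = ss,
           direction_class = cls, move_start = ms, move_end = me, ipd = ipd)
}
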