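#' Minimum-jerk displacement profile
#'
#' Normalised minimum-jerk (quintic) position profile, the standard model of
#' smooth point-to-point reaching/stepping: `s(u) = 10u^3 - 15u^4 + 6u^5` for
#' phase `u` in \[0, 1\]. A step of amplitude `D` metres over `T` seconds
#' following this profile has a bell-shaped velocity curve with closed-form
#' peak speed `15 D / (8 T)` at mid-movement.
#'
#' @param t Time since movement onset, s (vectorised).
#' @param amplitude Signed step amplitude, m.
#' @param duration Movement duration, s.
#' @return Displacement at `t`, m (0 before onset, `amplitude` after `duration`).
#' @export
#' @examples
#' minimum_jerk(seq(0, 0.8, 0.1), amplitude = 0.5, duration = 0.8)
minimum_jerk <- function(t, amplitude, duration) {
  u <- pmin(pmax(t / duration, 0), 1)
  amplitude * (10 * u^3 - 15 * u^4 + 6 * u^5)
}

#' Peak speed of a minimum-jerk step
#' @param amplitude Step amplitude, m.
#' @param duration Step duration, s.
#' @return Peak speed, m/s (`15 * amplitude / (8 * duration)`).
#' @export
minimum_jerk_peak_speed <- function(amplitude, duration) {
  15 * abs(amplitude) / (8 * duration)
}

# band-limited sway surrogate: sum of k sinusoids, frequencies below freq_max,
# total variance sway_sd^2; consumes 2k uniforms from the session RNG
sway_track <- function(t, sway_sd, freq_max, k = 3L) {
  if (sway_sd <= 0) return(numeric(length(t)))
  f <- runif(k, 0.05, freq_max)
  phi <- runif(k, 0, 2 * pi)
  amp <- sway_sd * sqrt(2 / k)
  rowSums(vapply(seq_len(k),
                 function(i) amp * sin(2 * pi * f[i] * t + phi[i]),
                 numeric(length(t))))
}

rating_from_attraction <- function(a, cutpoints) {
  1L + vapply(a, function(v) sum(v > cutpoints), integer(1))
}

# time after movement start at which a minimum-jerk step of amplitude D (m)
# and duration T (s) first reaches the given speed; the generator anchors
# each trial's nominal onset to this crossing so that threshold-based onset
# detection recovers the injected latency
minimum_jerk_threshold_time <- function(amplitude, duration, threshold) {
  vmax <- minimum_jerk_peak_speed(amplitude, duration)
  if (threshold >= vmax) {
    aat_abort("onset threshold exceeds the step's peak speed", "bad_trial")
  }
  f <- function(u) abs(amplitude) / duration * 30 * u^2 * (1 - u)^2 - threshold
  stats::uniroot(f, c(0, 0.5), tol = 1e-12)$root * duration
}

#' Generate a synthetic cohort skeleton
#'
#' Draws subjects, avatars, subject-avatar latent attractions and the full
#' grid of AAT and IPD trial slots, without simulating trajectories. Latent
#' attraction is high when the avatar's sex matches the subject's preferred
#' sex (female for gynophilic, male for androphilic subjects) and low
#' otherwise, plus pair-level Gaussian noise. In the AAT grid each avatar is
#' approached and avoided `aat_reps_per_mapping` times via two
#' response-mapping blocks (block 1: approach female / avoid male; block 2
#' reversed).
#'
#' Reseeds the session RNG from `config$seed`, so equal configurations yield
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param params A [generative_params()].
#' @return A list with tibbles `subjects`, `avatars`, `pairs`, `aat_slots`,
#'   `ipd_slots`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = generative_params()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(params, "generative_params"))
  set.seed(config$seed)

  n_sub <- config$n_gynophilic + config$n_androphilic
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    orientation = rep(c("gynophilic", "androphilic"),
                      c(config$n_gynophilic, config$n_androphilic)),
    u_rt  = rnorm(n_sub, 0, params$subject_sd$rt),
    u_pv  = rnorm(n_sub, 0, params$subject_sd$peak_vel),
    u_step = rnorm(n_sub, 0, params$subject_sd$step),
    u_ipd = rnorm(n_sub, 0, params$subject_sd$ipd)
  )

  n_av <- config$n_male_avatars + config$n_female_avatars
  avatars <- tibble(
    avatar_id = sprintf("A%02d", seq_len(n_av)),
    avatar_sex = rep(c("male", "female"),
                     c(config$n_male_avatars, config$n_female_avatars)),
    v_rt  = rnorm(n_av, 0, params$stimulus_sd$rt),
    v_pv  = rnorm(n_av, 0, params$stimulus_sd$peak_vel),
    v_step = rnorm(n_av, 0, params$stimulus_sd$step),
    v_ipd = rnorm(n_av, 0, params$stimulus_sd$ipd)
  )

  pairs <- tidyr::crossing(subject_id = subjects$subject_id,
                           avatar_id = avatars$avatar_id) |>
    left_join(subjects[, c("subject_id", "orientation")], by = "subject_id") |>
    left_join(avatars[, c("avatar_id", "avatar_sex")], by = "avatar_id") |>
    mutate(
      preferred = ifelse(.data$orientation == "gynophilic", "female", "male"),
      latent_attraction = ifelse(.data$avatar_sex == .data$preferred, 1, -1) *
        params$attraction_match_effect +
        rnorm(n(), 0, params$attraction_pair_sd),
      rating = rating_from_attraction(.data$latent_attraction,
                                      params$rating_cutpoints)
    ) |>
    select(-"preferred")

  aat_slots <- tidyr::crossing(subject_id = subjects$subject_id,
                               block = 1:2,
                               avatar_id = avatars$avatar_id,
                               rep = seq_len(config$aat_reps_per_mapping)) |>
    left_join(avatars[, c("avatar_id", "avatar_sex")], by = "avatar_id") |>
    mutate(direction = ifelse((.data$block == 1) == (.data$avatar_sex == "female"),
                              "approach", "avoidance")) |>
    left_join(subjects[, c("subject_id", "orientation")], by = "subject_id") |>
    arrange(.data$subject_id, .data$block, .data$avatar_id, .data$rep)

  ipd_slots <- tidyr::crossing(subject_id = subjects$subject_id,
                               avatar_id = avatars$avatar_id,
                               rep = seq_len(config$ipd_reps)) |>
    left_join(avatars[, c("avatar_id", "avatar_sex")], by = "avatar_id") |>
    left_join(subjects[, c("subject_id", "orientation")], by = "subject_id") |>
    arrange(.data$subject_id, .data$avatar_id, .data$rep)

  list(subjects = subjects, avatars = avatars, pairs = pairs,
       aat_slots = aat_slots, ipd_slots = ipd_slots)
}

# effect codes used by both generator and models
code_orientation <- function(x) ifelse(x == "androphilic", 0.5, -0.5)
code_avatar_sex <- function(x) ifelse(x == "female", 0.5, -0.5)
code_direction <- function(x) ifelse(x == "approach", 0.5, -0.5)

#' Simulate one AAT trial trajectory
#'
#' Builds the head-position time series of a single approach-avoidance trial:
#' postural sway from stimulus onset, then a minimum-jerk step of the trial's
#' true amplitude starting at the true onset latency (forward toward the
#' avatar for approach, backward for avoidance), then post-movement sway
#' until the rating-onset marker. Step duration is set so the minimum-jerk
#' profile attains the trial's true peak speed. Consumes the session RNG
#' (sway phases only).
#'
#' @param trial One-row data frame with `true_rt_ms`, `true_step_cm`,
#'   `true_peak_vel`, `direction`, `start_distance`.
#' @param params A [generative_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param post_window Sway tail after movement end, s.
#' @param max_duration Longest admissible step duration, s (longer steps
#'   are rejected as inconsistent with a single discrete trial).
#' @return Tibble with columns `t`, `x`, `y`, `z` plus attributes
#'   `stimulus_onset`, `rating_onset`.
#' @export
simulate_aat_trial <- function(trial, params = generative_params(),
                               sample_rate = 85, post_window = 0.4,
                               max_duration = 5) {
  stopifnot(nrow(trial) == 1)
  onset <- trial$true_rt_ms / 1000
  step_m <- trial$true_step_cm / 100
  dur <- 15 * step_m / (8 * trial$true_peak_vel)
  # the nominal onset is where the speed profile crosses the onset
  # threshold, so the movement itself starts slightly earlier
  lead <- minimum_jerk_threshold_time(step_m, dur, params$onset_threshold)
  move_start <- max(onset - lead, 0)
  rating_onset <- move_start + dur + post_window
  if (dur > max_duration) {
    aat_abort("step duration exceeds the trial window", "bad_trial")
  }
  tt <- seq(0, rating_onset, by = 1 / sample_rate)
  sign <- if (trial$direction == "approach") 1 else -1
  z <- sign * minimum_jerk(tt - move_start, step_m, dur) +
    sway_track(tt, params$sway_sd, params$sway_freq_max)
  x <- sway_track(tt, params$sway_sd, params$sway_freq_max)
  out <- tibble(t = tt, x = x, y = 1.7, z = z)
  attr(out, "stimulus_onset") <- 0
  attr(out, "rating_onset") <- rating_onset
  out
}

#' Simulate one IPD trial trajectory
#'
#' Forward walk from the 2 m start position toward the avatar, decelerating
#' and stopping at the trial's true stopping distance, followed by sway until
#' the confirm-press marker. The walk follows a minimum-jerk displacement
#' profile whose duration is set by the trial's true peak speed.
#'
#' @param trial One-row data frame with `true_stop_cm`, `true_peak_vel`,
#'   `onset_s` (walk start latency) and `start_distance` (m).
#' @param params A [generative_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param post_window Sway tail between stop and confirm press, s.
#' @return Tibble `t`, `x`, `y`, `z` with attributes `stimulus_onset` and
#'   `confirm_press`.
#' @export
simulate_ipd_trial <- function(trial, params = generative_params(),
                               sample_rate = 85, post_window = 0.3) {
  stopifnot(nrow(trial) == 1)
  if (trial$true_stop_cm <= 0) {
    aat_abort("stopping distance must be positive", "bad_trial")
  }
  amp <- trial$start_distance - trial$true_stop_cm / 100
  if (amp <= 0) aat_abort("stop distance beyond start distance", "bad_trial")
  dur <- 15 * amp / (8 * trial$true_peak_vel)
  confirm <- trial$onset_s + dur + post_window
  tt <- seq(0, confirm, by = 1 / sample_rate)
  z <- minimum_jerk(tt - trial$onset_s, amp, dur) +
    sway_track(tt, params$sway_sd, params$sway_freq_max)
  x <- sway_track(tt, params$sway_sd, params$sway_freq_max)
  out <- tibble(t = tt, x = x, y = 1.7, z = z)
  attr(out, "stimulus_onset") <- 0
  attr(out, "confirm_press") <- confirm
  out
}

#' Simulate a complete synthetic cohort
#'
#' Generates the cohort skeleton with [generate_cohort()], draws per-trial
#' true kinematics from the generative linear models (condition effects,
#' latent attraction, subject and stimulus random intercepts, residual
#' noise), and synthesises every trial's head-position trajectory. The whole
#' run is a deterministic function of `config$seed`.
#'
#' True AAT initiation RT is log-normal on the log2 scale:
#' `log2(RT_ms) = baseline + effects + noise`. True step size, peak velocity
#' and IPD are Gaussian on their natural scales, truncated away from
#' degenerate values (steps below 5 cm, peak speeds below twice the 0.10 m/s
#' onset threshold, stops outside (5 cm, start - 5 cm), resampled).
#'
#' @param config A [cohort_config()].
#' @param params A [generative_params()].
#' @return A list of class `aat_cohort`: tibbles `subjects`, `avatars`,
#'   `trials` (one row per trial with metadata and rating), `truth` (ground
#'   truth per trial), `samples` (trajectory rows `trial_id, t, x, y, z`),
#'   plus `config` and `params`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            params = generative_params()) {
  cohort <- generate_cohort(config, params)
  subjects <- cohort$subjects; avatars <- cohort$avatars

  aat <- cohort$aat_slots |>
    left_join(cohort$pairs[, c("subject_id", "avatar_id",
                               "latent_attraction", "rating")],
              by = c("subject_id", "avatar_id")) |>
    left_join(subjects[, c("subject_id", "u_rt", "u_pv", "u_step")],
              by = "subject_id") |>
    left_join(avatars[, c("avatar_id", "v_rt", "v_pv", "v_step")],
              by = "avatar_id")

  d <- code_direction(aat$direction)
  a <- aat$latent_attraction
  n <- nrow(aat)
  log2rt <- params$baseline_log2_rt + params$direction_effect * d +
    params$attraction_rt_slope * a +
    params$attraction_direction_interaction * a * d +
    aat$u_rt + aat$v_rt + rnorm(n, 0, params$residual_sd$rt)
  step <- params$baseline_step + params$attraction_step_slope * a +
    aat$u_step + aat$v_step + rnorm(n, 0, params$residual_sd$step)
  pv <- params$baseline_peak_vel + params$attraction_vel_slope * a +
    aat$u_pv + aat$v_pv + rnorm(n, 0, params$residual_sd$peak_vel)
  step <- pmax(step, 5)
  pv <- pmax(pv, 0.2)

  aat_trials <- tibble(
    trial_id = sprintf("T%05d", seq_len(n)),
    experiment = "AAT",
    subject_id = aat$subject_id, avatar_id = aat$avatar_id,
    orientation = aat$orientation, avatar_sex = aat$avatar_sex,
    direction = aat$direction, block = aat$block,
    rating = aat$rating,
    start_distance = 1.5, avatar_x = 0, avatar_z = 1.5,
    stimulus_onset = 0,
    true_rt_ms = 2^log2rt, true_step_cm = step, true_peak_vel = pv,
    true_stop_cm = NA_real_, latent_attraction = a
  )

  ipd <- cohort$ipd_slots |>
    left_join(cohort$pairs[, c("subject_id", "avatar_id",
                               "latent_attraction", "rating")],
              by = c("subject_id", "avatar_id")) |>
    left_join(subjects[, c("subject_id", "u_ipd", "u_pv")],
              by = "subject_id") |>
    left_join(avatars[, c("avatar_id", "v_ipd", "v_pv")],
              by = "avatar_id")
  m <- nrow(ipd)
  o <- code_orientation(ipd$orientation)
  s <- code_avatar_sex(ipd$avatar_sex)
  ai <- ipd$latent_attraction
  stop_cm <- params$baseline_ipd + params$ipd_sex_effect * s +
    params$ipd_orientation_effect * o + params$ipd_interaction * o * s +
    params$ipd_attraction_slope * ai +
    ipd$u_ipd + ipd$v_ipd + rnorm(m, 0, params$residual_sd$ipd)
  # resample stops outside the physically admissible band
  bad <- which(stop_cm <= 5 | stop_cm >= 195)
  while (length(bad) > 0) {
    stop_cm[bad] <- params$baseline_ipd + params$ipd_sex_effect * s[bad] +
      params$ipd_orientation_effect * o[bad] +
      params$ipd_interaction * o[bad] * s[bad] +
      params$ipd_attraction_slope * ai[bad] +
      ipd$u_ipd[bad] + ipd$v_ipd[bad] +
      rnorm(length(bad), 0, params$residual_sd$ipd)
    bad <- which(stop_cm <= 5 | stop_cm >= 195)
  }
  walk_pv <- pmax(ipd$u_pv + ipd$v_pv + params$baseline_peak_vel +
                    params$attraction_vel_slope * ai +
                    rnorm(m, 0, params$residual_sd$peak_vel), 0.2)
  walk_onset <- runif(m, 0.4, 0.7)

  ipd_trials <- tibble(
    trial_id = sprintf("T%05d", n + seq_len(m)),
    experiment = "IPD",
    subject_id = ipd$subject_id, avatar_id = ipd$avatar_id,
    orientation = ipd$orientation, avatar_sex = ipd$avatar_sex,
    direction = NA_character_, block = NA_integer_,
    rating = ipd$rating,
    start_distance = 2.0, avatar_x = 0, avatar_z = 2.0,
    stimulus_onset = 0,
    true_rt_ms = NA_real_, true_step_cm = NA_real_, true_peak_vel = walk_pv,
    true_stop_cm = stop_cm, latent_attraction = ai
  )
  ipd_trials$onset_s <- walk_onset

  # trajectory synthesis
  rate <- config$sample_rate
  aat_mats <- vector("list", n)
  aat_rating_onset <- numeric(n)
  for (i in seq_len(n)) {
    tr <- simulate_aat_trial(aat_trials[i, ], params, rate)
    aat_rating_onset[i] <- attr(tr, "rating_onset")
    aat_mats[[i]] <- cbind(i, tr$t, tr$x, tr$y, tr$z)
  }
  ipd_mats <- vector("list", m)
  ipd_confirm <- numeric(m)
  for (j in seq_len(m)) {
    tr <- simulate_ipd_trial(ipd_trials[j, ], params, rate)
    ipd_confirm[j] <- attr(tr, "confirm_press")
    ipd_mats[[j]] <- cbind(n + j, tr$t, tr$x, tr$y, tr$z)
  }
  aat_trials$response_onset <- aat_rating_onset
  ipd_trials$response_onset <- ipd_confirm
  ipd_trials$onset_s <- NULL

  all_ids <- c(aat_trials$trial_id, ipd_trials$trial_id)
  sm <- do.call(rbind, c(aat_mats, ipd_mats))
  samples <- tibble(trial_id = all_ids[sm[, 1]],
                    t = sm[, 2], x = sm[, 3], y = sm[, 4], z = sm[, 5])

  trials <- bind_rows(aat_trials, ipd_trials)
  truth <- trials |>
    select("trial_id", "experiment", "subject_id", "avatar_id",
           "latent_attraction", "true_rt_ms", "true_step_cm",
           "true_peak_vel", "true_stop_cm")
  trials <- trials |>
    select(-"true_rt_ms", -"true_step_cm", -"true_peak_vel",
           -"true_stop_cm", -"latent_attraction")

  structure(list(subjects = subjects, avatars = avatars, trials = trials,
                 truth = truth, samples = samples,
                 config = config, params = params),
            class = "aat_cohort")
}

#' @export
print.aat_cohort <- function(x, ...) {
  cat("<aat_cohort>", nrow(x$subjects), "subjects,", nrow(x$avatars),
      "avatars,", nrow(x$trials), "trials,", nrow(x$samples),
      "trajectory samples\n")
  invisible(x)
}
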