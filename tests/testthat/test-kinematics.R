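test_that("resampling is idempotent on uniform input and interpolates linearly", {
  tt <- seq(0, 1, by = 1 / 85)
  s <- tibble::tibble(t = tt, x = sin(tt), y = 1.7, z = cos(tt))
  r <- resample_uniform(s, 85)
  expect_equal(r$x, s$x, tolerance = 1e-12)
  expect_equal(r$t, s$t, tolerance = 1e-12)

  two <- tibble::tibble(t = c(0, 1), x = c(0, 1), y = 0, z = 0)
  r2 <- resample_uniform(two, 4)
  expect_equal(r2$x, c(0, 0.25, 0.5, 0.75, 1))
})

test_that("resampling preserves linear trajectories under timestamp jitter", {
  set.seed(1)
  tt <- sort(runif(200, 0, 2))
  s <- tibble::tibble(t = tt, x = 0.3 * tt - 1, y = 1.7, z = -0.2 * tt + 4)
  r <- resample_uniform(s, 85)
  expect_equal(r$x, 0.3 * r$t - 1, tolerance = 1e-12)
  expect_equal(r$z, -0.2 * r$t + 4, tolerance = 1e-12)
})

test_that("resampling rejects duplicate timestamps", {
  s <- tibble::tibble(t = c(0, 0.1, 0.1, 0.3), x = 1:4, y = 0, z = 0)
  expect_error(resample_uniform(s), class = "aatkin_bad_trajectory")
})

test_that("smoothing reproduces polynomials up to the filter order", {
  tt <- seq(0, 2, by = 1 / 85)
  const <- tibble::tibble(t = tt, x = rep(2.5, length(tt)), y = 1, z = -3)
  expect_equal(smooth_trajectory(const)$x, const$x, tolerance = 1e-12)
  quad <- tibble::tibble(t = tt, x = 1 + 0.5 * tt - 2 * tt^2, y = 1.7,
                         z = 0.3 * tt^2)
  sm <- smooth_trajectory(quad)
  expect_equal(sm$x, quad$x, tolerance = 1e-9)
  expect_equal(sm$z, quad$z, tolerance = 1e-9)
})

test_that("smoothing errors on series shorter than the window", {
  s <- tibble::tibble(t = (0:5) / 85, x = rnorm(6), y = 0, z = 0)
  expect_error(smooth_trajectory(s), regexp = "11",
               class = "aatkin_too_short")
})

test_that("interior smoothing equals the brute-force per-window polynomial fit", {
  set.seed(42)
  cfg <- kinematic_config()
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    v <- cumsum(rnorm(n, 0, 0.01)) + 0.1 * seq_len(n) / n
    sm <- aatkin:::sg_smooth_series(v, cfg$sg_window, cfg$sg_order)
    interior <- 6:(n - 5)
    oracle <- vapply(interior, function(i) oracle_sg_point(v, i, 11, 2),
                     numeric(1))
    expect_equal(sm[interior], oracle, tolerance = 1e-9)
  }
})

test_that("speed is zero at rest and exact for uniform motion", {
  tt <- seq(0, 1, by = 1 / 85)
  still <- tibble::tibble(t = tt, x = 1, y = 1.7, z = 2)
  expect_equal(compute_speed(still), rep(0, length(tt)))
  moving <- tibble::tibble(t = tt, x = tt, y = 1.7, z = 0)
  expect_equal(compute_speed(moving), rep(1, length(tt)), tolerance = 1e-10)
})

test_that("peak speed of a sampled minimum-jerk step matches the closed form", {
  tt <- seq(0, 1.2, by = 1 / 85)
  s <- tibble::tibble(t = tt, x = 0, y = 1.7,
                      z = minimum_jerk(tt - 0.2, 0.5, 0.8))
  spd <- compute_speed(s)
  expect_equal(max(spd), 15 * 0.5 / (8 * 0.8), tolerance = 0.02)
})

test_that("onset detection matches the exhaustive scan oracle", {
  cfg <- kinematic_config()
  set.seed(7)
  for (rep in 1:1000) {
    n <- sample(20:120, 1)
    spd <- abs(rnorm(n, 0.08, 0.05))
    tt <- seq_len(n) / 85
    got <- detect_onset(spd, tt, 0, cfg)$onset
    want <- oracle_onset(spd, tt, cfg$onset_threshold, cfg$sustain_samples)
    expect_identical(got, want)
  }
})

test_that("onset is missing when speed never sustains the threshold", {
  tt <- (1:50) / 85
  expect_true(is.na(detect_onset(rep(0.05, 50), tt)$onset))
  # a 2-sample spike does not count with sustain_samples = 3
  spd <- rep(0.05, 50); spd[20:21] <- 0.5
  expect_true(is.na(detect_onset(spd, tt)$onset))
  spd[20:22] <- 0.5
  expect_equal(detect_onset(spd, tt)$onset, tt[20])
  expect_equal(detect_onset(spd, tt)$rt_ms, tt[20] * 1000)
})

test_that("movement extraction isolates the first movement segment", {
  # two separated minimum-jerk steps; only the first should be measured
  tt <- seq(0, 4, by = 1 / 85)
  z <- minimum_jerk(tt - 0.5, 0.4, 0.6) + minimum_jerk(tt - 2.5, 0.3, 0.5)
  s <- tibble::tibble(t = tt, x = 0, y = 1.7, z = z)
  spd <- compute_speed(s)
  on <- detect_onset(spd, tt)
  mv <- extract_movement(s, spd, on$onset, c(0, 1))
  # the first step ends around t = 1.1; the second must be excluded
  expect_lt(mv$move_end, 2.0)
  expect_equal(mv$step_size, 40, tolerance = 1.5)
  expect_equal(mv$peak_velocity, 15 * 0.4 / (8 * 0.6), tolerance = 0.02)
  # sway tail after the step is excluded by the cutoff rule
  expect_lt(mv$move_end, on$onset + 0.8)
})

test_that("direction classification follows the 10 cm opposite-excursion rule", {
  tt <- seq(0, 2, by = 1 / 85)
  axis <- c(0, 1)
  fwd <- tibble::tibble(t = tt, x = 0, y = 1.7,
                        z = minimum_jerk(tt - 0.4, 0.5, 0.8))
  spd <- compute_speed(fwd)
  on <- detect_onset(spd, tt)$onset
  expect_equal(classify_direction(fwd, "approach", on, axis), "correct")
  expect_equal(classify_direction(fwd, "avoidance", on, axis), "incorrect")

  # a 12 cm backward excursion then forward: incorrect for approach
  zig <- tibble::tibble(t = tt, x = 0, y = 1.7,
                        z = minimum_jerk(tt - 0.3, -0.12, 0.4) +
                          minimum_jerk(tt - 1.0, 0.5, 0.6))
  spd2 <- compute_speed(zig)
  on2 <- detect_onset(spd2, tt)$onset
  expect_equal(classify_direction(zig, "approach", on2, axis), "incorrect")

  # no onset before the response marker: missing
  expect_equal(classify_direction(fwd, "approach", NA_real_, axis), "missing")
  expect_equal(classify_direction(fwd, "approach", 1.5, axis,
                                  response_onset = 1.0), "missing")
  expect_error(classify_direction(fwd, "sideways", on, axis),
               class = "aatkin_bad_direction")
})

test_that("IPD is the horizontal head-avatar distance at the confirm press", {
  tt <- seq(0, 1, by = 1 / 85)
  s <- tibble::tibble(t = tt, x = 0, y = 1.7, z = 0)
  spd <- rep(0.5, length(tt))  # nominal movement so the trial is not missing
  at_avatar <- compute_ipd(s, spd, 1, c(0, 0))
  expect_equal(at_avatar$ipd, 0)
  triangle <- compute_ipd(s, spd, 1, c(0.3, 0.4))
  expect_equal(triangle$ipd, 50)
  expect_error(compute_ipd(s, spd, NA, c(0, 0)), class = "aatkin_no_marker")
  # no supra-threshold movement: flagged missing
  still <- compute_ipd(s, rep(0.01, length(tt)), 1, c(0.3, 0.4))
  expect_true(still$missing)
})

test_that("step size and peak velocity are invariant under horizontal rotation", {
  pars <- generative_params(sway_sd = 0)
  trial <- tibble::tibble(true_rt_ms = 450, true_step_cm = 48,
                          true_peak_vel = 0.9, direction = "approach",
                          start_distance = 1.5)
  base <- simulate_aat_trial(trial, pars, 85)
  cfg <- kinematic_config()
  run <- function(s, avatar) {
    sm <- smooth_trajectory(s, cfg)
    spd <- compute_speed(sm)
    on <- detect_onset(spd, sm$t, 0, cfg)
    ax <- aatkin:::subject_avatar_axis(sm$x[1], sm$z[1], avatar[1], avatar[2])
    extract_movement(sm, spd, on$onset, ax, cfg)
  }
  ref <- run(base, c(0, 1.5))
  for (theta in c(0.4, 1.2, 2.9)) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
    xz <- cbind(base$x, base$z) %*% t(R)
    rot <- tibble::tibble(t = base$t, x = xz[, 1], y = base$y, z = xz[, 2])
    av <- drop(R %*% c(0, 1.5))
    got <- run(rot, av)
    expect_equal(got$peak_velocity, ref$peak_velocity, tolerance = 1e-9)
    expect_equal(got$step_size, ref$step_size, tolerance = 1e-9)
  }
})

test_that("noise-free extraction recovers injected kinematics within a sample", {
  pars <- generative_params(
    sway_sd = 0,
    subject_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    stimulus_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    residual_sd = list(rt = 0.1, peak_vel = 0.05, step = 4, ipd = 6))
  co <- simulate_cohort(cohort_config(n_gynophilic = 2, n_androphilic = 1,
                                      n_male_avatars = 2, n_female_avatars = 2,
                                      aat_reps_per_mapping = 1, ipd_reps = 1,
                                      seed = 21), pars)
  ex <- extract_kinematics(co$trials, co$samples)
  cmp <- dplyr::left_join(ex, co$truth, by = "trial_id")
  aat <- cmp[cmp$experiment.x == "AAT" & cmp$direction_class == "correct", ]
  dt_ms <- 1000 / 85
  expect_true(all(abs(aat$rt_ms - aat$true_rt_ms) <= dt_ms))
  # one sample period of displacement at each trial's peak speed, plus the
  # sub-threshold movement tails excluded by the onset/offset criteria
  tol_cm <- aat$true_peak_vel * (1 / 85) * 100 + 1
  expect_true(all(abs(aat$step_size - aat$true_step_cm) <= tol_cm))
  expect_true(all(abs(aat$peak_velocity - aat$true_peak_vel) <=
                    aat$true_peak_vel * 0.02))
  ipd <- cmp[cmp$experiment.x == "IPD", ]
  expect_true(all(abs(ipd$ipd - ipd$true_stop_cm) < 0.2))
})
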