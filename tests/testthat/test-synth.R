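test_that("default design reproduces the study layout", {
  co <- generate_cohort(cohort_config(), generative_params())
  expect_equal(nrow(co$subjects), 72)
  expect_equal(sum(co$subjects$orientation == "androphilic"), 24)
  expect_equal(nrow(co$avatars), 20)
  expect_equal(nrow(co$aat_slots), 72 * 160)
  expect_equal(nrow(co$ipd_slots), 72 * 40)
  # each avatar approached and avoided equally often per subject
  one <- dplyr::count(co$aat_slots[co$aat_slots$subject_id == "S001", ],
                      avatar_id, direction)
  expect_true(all(one$n == 4))
})

test_that("small designs enumerate trial slots exactly", {
  co <- generate_cohort(
    cohort_config(n_gynophilic = 1, n_androphilic = 1,
                  n_male_avatars = 1, n_female_avatars = 1,
                  aat_reps_per_mapping = 1, ipd_reps = 1),
    generative_params())
  expect_equal(nrow(co$aat_slots), 2 * 2 * 2 * 1)
  expect_equal(nrow(co$ipd_slots), 2 * 2)
})

test_that("invalid design counts are rejected", {
  expect_error(cohort_config(n_gynophilic = 0), class = "aatkin_bad_config")
  expect_error(cohort_config(sample_rate = -1), class = "aatkin_bad_config")
  expect_error(generative_params(rating_cutpoints = c(1, 2, 2, 3)),
               class = "aatkin_bad_params")
  expect_error(generative_params(residual_sd = list(rt = 0, peak_vel = 1,
                                                    step = 1, ipd = 1)),
               class = "aatkin_bad_params")
})

test_that("seeded cohort simulation is exactly reproducible", {
  cc <- cohort_config(n_gynophilic = 2, n_androphilic = 1,
                      n_male_avatars = 2, n_female_avatars = 2,
                      aat_reps_per_mapping = 1, ipd_reps = 1, seed = 42)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_identical(a$samples, b$samples)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
})

test_that("latent attraction tracks preferred avatar sex and sets ratings", {
  pars <- generative_params(attraction_pair_sd = 1e-9)
  co <- generate_cohort(cohort_config(n_gynophilic = 2, n_androphilic = 2,
                                      seed = 3), pars)
  pref <- with(co$pairs,
               (orientation == "gynophilic") == (avatar_sex == "female"))
  expect_true(all(co$pairs$latent_attraction[pref] > 0.99))
  expect_true(all(co$pairs$latent_attraction[!pref] < -0.99))
  # default +/-1 attraction sits between the inner and outer cutpoints
  expect_equal(unique(co$pairs$rating[pref]), 4L)
  expect_equal(unique(co$pairs$rating[!pref]), 2L)
  # ordinal boundaries: attraction beyond the outer cutpoints saturates
  extreme <- generate_cohort(cohort_config(n_gynophilic = 2,
                                           n_androphilic = 2, seed = 3),
                             generative_params(attraction_match_effect = 3,
                                               attraction_pair_sd = 1e-9))
  pref3 <- with(extreme$pairs,
                (orientation == "gynophilic") == (avatar_sex == "female"))
  expect_equal(unique(extreme$pairs$rating[pref3]), 5L)
  expect_equal(unique(extreme$pairs$rating[!pref3]), 1L)
})

test_that("noise-free trials of one subject are identical within direction", {
  pars <- generative_params(
    sway_sd = 0, attraction_rt_slope = 0,
    attraction_direction_interaction = 0, attraction_step_slope = 0,
    attraction_vel_slope = 0, attraction_pair_sd = 1e-12,
    subject_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    stimulus_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    residual_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12))
  co <- simulate_cohort(cohort_config(n_gynophilic = 1, n_androphilic = 1,
                                      n_male_avatars = 1, n_female_avatars = 1,
                                      aat_reps_per_mapping = 2, seed = 5), pars)
  tr <- dplyr::filter(co$truth, experiment == "AAT", subject_id == "S001")
  tr <- dplyr::left_join(tr, co$trials[, c("trial_id", "direction")],
                         "trial_id")
  for (dir in c("approach", "avoidance")) {
    g <- tr[tr$direction == dir, ]
    expect_lt(diff(range(g$true_rt_ms)), 1e-6)
    expect_lt(diff(range(g$true_step_cm)), 1e-6)
  }
  # approach onsets faster than avoidance under the negative direction effect
  expect_lt(mean(tr$true_rt_ms[tr$direction == "approach"]),
            mean(tr$true_rt_ms[tr$direction == "avoidance"]))
})

test_that("minimum-jerk step has the closed-form peak speed", {
  t <- seq(0, 0.8, length.out = 20001)
  x <- minimum_jerk(t, amplitude = 0.5, duration = 0.8)
  v <- diff(x) / diff(t)
  expect_equal(max(v), minimum_jerk_peak_speed(0.5, 0.8), tolerance = 1e-6)
  expect_equal(minimum_jerk_peak_speed(0.5, 0.8), 15 * 0.5 / (8 * 0.8))
  # profile is monotone and lands exactly on the amplitude
  expect_true(all(diff(x) >= 0))
  expect_equal(x[length(x)], 0.5)
})

test_that("sway speed stays below the documented bound and the 10 cm/s cutoff", {
  set.seed(99)
  t <- seq(0, 5, by = 1 / 85)
  bound <- sway_speed_bound(0.008, 0.3)
  expect_lt(bound, 0.10)
  for (i in 1:20) {
    x <- aatkin:::sway_track(t, 0.008, 0.3)
    z <- aatkin:::sway_track(t, 0.008, 0.3)
    spd <- sqrt(diff(x)^2 + diff(z)^2) * 85
    expect_lt(max(spd), bound)
  }
})

test_that("increasing attraction_step_slope increases preferred-sex step size", {
  cc <- cohort_config(n_gynophilic = 3, n_androphilic = 3,
                      n_male_avatars = 2, n_female_avatars = 2,
                      aat_reps_per_mapping = 1, seed = 11)
  mean_pref_step <- function(slope) {
    co <- simulate_cohort(cc, generative_params(attraction_step_slope = slope))
    tr <- dplyr::left_join(co$truth, co$trials[, c("trial_id", "orientation",
                                                   "avatar_sex")], "trial_id")
    pref <- (tr$orientation == "gynophilic") == (tr$avatar_sex == "female")
    mean(tr$true_step_cm[tr$experiment == "AAT" & pref])
  }
  steps <- vapply(c(0, 2, 4), mean_pref_step, numeric(1))
  expect_true(all(diff(steps) > 0))
})

test_that("degenerate IPD generator stops exactly at the baseline distance", {
  pars <- generative_params(
    baseline_ipd = 97, ipd_sex_effect = 0, ipd_orientation_effect = 0,
    ipd_interaction = 0, ipd_attraction_slope = 0, sway_sd = 0,
    subject_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    stimulus_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12),
    residual_sd = list(rt = 1e-12, peak_vel = 1e-12, step = 1e-12, ipd = 1e-12))
  co <- simulate_cohort(cohort_config(n_gynophilic = 1, n_androphilic = 1,
                                      n_male_avatars = 1, n_female_avatars = 1,
                                      aat_reps_per_mapping = 1, ipd_reps = 1,
                                      seed = 2), pars)
  ipd_truth <- co$truth$true_stop_cm[co$truth$experiment == "IPD"]
  expect_equal(ipd_truth, rep(97, length(ipd_truth)), tolerance = 1e-6)
  # and the extractor recovers it to within a millimetre
  ex <- extract_kinematics(co$trials, co$samples)
  got <- ex$ipd[ex$experiment == "IPD"]
  expect_equal(got, rep(97, length(got)), tolerance = 0.1 / 97)
})

test_that("negative avatar-sex effect moves female-avatar stops closer", {
  co <- simulate_cohort(cohort_config(n_gynophilic = 6, n_androphilic = 6,
                                      n_male_avatars = 4, n_female_avatars = 4,
                                      aat_reps_per_mapping = 1, ipd_reps = 2,
                                      seed = 8),
                        generative_params(ipd_sex_effect = -30,
                                          ipd_orientation_effect = 0,
                                          ipd_interaction = 0,
                                          ipd_attraction_slope = 0))
  tr <- dplyr::left_join(co$truth, co$trials[, c("trial_id", "avatar_sex")],
                         "trial_id")
  tr <- tr[tr$experiment == "IPD", ]
  expect_lt(mean(tr$true_stop_cm[tr$avatar_sex == "female"]),
            mean(tr$true_stop_cm[tr$avatar_sex == "male"]))
})

test_that("a step longer than the admissible window is rejected", {
  trial <- tibble::tibble(true_rt_ms = 500, true_step_cm = 600,
                          true_peak_vel = 0.2, direction = "approach",
                          start_distance = 1.5)
  expect_error(simulate_aat_trial(trial, generative_params(), 85,
                                  max_duration = 2),
               class = "aatkin_bad_trial")
})
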