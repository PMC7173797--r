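#' Cohort design configuration
#'
#' Describes the experimental design of a simulated cohort: group sizes,
#' stimulus set, trial counts and the head-tracker sampling rate. The defaults
#' reproduce the design of the study the package models: 72 male subjects
#' (48 gynophilic, 24 androphilic), 20 avatars (10 male, 10 female), 160
#' approach-avoidance (AAT) trials per subject (each avatar approached and
#' avoided four times across two response-mapping blocks) and 40
#' interpersonal-distance (IPD) trials per subject (each avatar twice), with
#' head position sampled at about 85 Hz.
#'
#' @param n_gynophilic,n_androphilic Number of subjects per sexual-orientation
#'   group.
#' @param n_male_avatars,n_female_avatars Number of avatars per avatar sex.
#' @param aat_reps_per_mapping Times each avatar is shown under each reaction
#'   direction (AAT trials per subject = 2 directions x avatars x reps).
#' @param ipd_reps Times each avatar is shown in the IPD task.
#' @param sample_rate Tracker sampling rate in Hz.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n_gynophilic = 4, n_androphilic = 2, aat_reps_per_mapping = 1)
cohort_config <- function(n_gynophilic = 48, n_androphilic = 24,
                          n_male_avatars = 10, n_female_avatars = 10,
                          aat_reps_per_mapping = 4, ipd_reps = 2,
                          sample_rate = 85, seed = 1L) {
  counts <- c(n_gynophilic = n_gynophilic, n_androphilic = n_androphilic,
              n_male_avatars = n_male_avatars, n_female_avatars = n_female_avatars,
              aat_reps_per_mapping = aat_reps_per_mapping, ipd_reps = ipd_reps)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    aat_abort("all design counts must be integers >= 1", "bad_config")
  }
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    aat_abort("sample_rate must be > 0", "bad_config")
  }
  structure(list(
    n_gynophilic = as.integer(n_gynophilic),
    n_androphilic = as.integer(n_androphilic),
    n_male_avatars = as.integer(n_male_avatars),
    n_female_avatars = as.integer(n_female_avatars),
    aat_reps_per_mapping = as.integer(aat_reps_per_mapping),
    ipd_reps = as.integer(ipd_reps),
    sample_rate = sample_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generative parameters for the synthetic cohort
#'
#' Parameters of the data-generating process used by [simulate_cohort()].
#' Outcome models are linear on the analysis scale of each dependent variable
#' (log2 milliseconds for initiation RT, cm for step size and IPD, m/s for
#' peak velocity), with effect-coded condition effects, a per-pair latent
#' attraction covariate, Gaussian subject and stimulus random intercepts and
#' Gaussian residual noise.
#'
#' Latent attraction for a subject-avatar pair is `+attraction_match_effect`
#' when the avatar's sex matches the subject's preferred sex and
#' `-attraction_match_effect` otherwise, plus `N(0, attraction_pair_sd)`
#' pair-level noise; ratings arise by thresholding this latent value at
#' `rating_cutpoints`.
#'
#' Default effect magnitudes point in the directions reported for this
#' paradigm: approach onsets faster than avoidance, larger/faster steps and
#' shorter stopping distances for attractive avatars, shorter IPD for female
#' avatars and for androphilic subjects, and a positive sex-by-orientation
#' IPD interaction.
#'
#' @param baseline_log2_rt Grand mean initiation RT, log2(ms).
#' @param direction_effect Reaction-direction effect on log2 RT
#'   (approach coded +0.5, avoidance -0.5).
#' @param attraction_rt_slope Log2-RT change per unit latent attraction.
#' @param attraction_direction_interaction Attraction-by-direction
#'   interaction on log2 RT.
#' @param baseline_step Grand mean step size, cm.
#' @param attraction_step_slope Step-size change per attraction unit, cm.
#' @param baseline_peak_vel Grand mean peak velocity, m/s.
#' @param attraction_vel_slope Peak-velocity change per attraction unit, m/s.
#' @param baseline_ipd Grand mean stopping distance, cm.
#' @param ipd_sex_effect Avatar-sex effect on IPD (female +0.5, male -0.5), cm.
#' @param ipd_orientation_effect Orientation effect on IPD
#'   (gynophilic -0.5, androphilic +0.5), cm.
#' @param ipd_interaction Orientation-by-avatar-sex interaction on IPD, cm.
#' @param ipd_attraction_slope IPD change per attraction unit, cm.
#' @param subject_sd,stimulus_sd,residual_sd Named lists of dispersions per
#'   dependent variable (`rt` in log2 units, `peak_vel` m/s, `step` cm,
#'   `ipd` cm).
#' @param sway_sd Standard deviation of postural sway per horizontal axis, m.
#' @param sway_freq_max Upper band edge of the sway process, Hz. Together with
#'   `sway_sd` this bounds sway speed (see [sway_speed_bound()]).
#' @param step_duration Reference step duration, s; the realised duration of
#'   each trial's step is set so the minimum-jerk profile attains the trial's
#'   generated peak velocity.
#' @param onset_threshold Speed criterion (m/s) that operationally defines
#'   movement onset; each simulated step is timed so its speed profile
#'   crosses this value exactly at the trial's sampled onset latency.
#' @param rating_cutpoints Four increasing thresholds mapping latent
#'   attraction to the 1-5 rating scale.
#' @param attraction_match_effect Latent-attraction shift for preferred-sex
#'   avatars (mirrored for non-preferred).
#' @param attraction_pair_sd SD of pair-level attraction noise.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(baseline_log2_rt = 9.20,
                              direction_effect = -0.10,
                              attraction_rt_slope = -0.01,
                              attraction_direction_interaction = -0.04,
                              baseline_step = 53,
                              attraction_step_slope = 1.3,
                              baseline_peak_vel = 0.85,
                              attraction_vel_slope = 0.015,
                              baseline_ipd = 97,
                              ipd_sex_effect = -6.7,
                              ipd_orientation_effect = -13.2,
                              ipd_interaction = 9.8,
                              ipd_attraction_slope = -3.5,
                              subject_sd = list(rt = 0.15, peak_vel = 0.10,
                                                step = 6, ipd = 15),
                              stimulus_sd = list(rt = 0.02, peak_vel = 0.02,
                                                 step = 1.5, ipd = 3),
                              residual_sd = list(rt = 0.28, peak_vel = 0.12,
                                                 step = 7, ipd = 8),
                              sway_sd = 0.008,
                              sway_freq_max = 0.3,
                              step_duration = 0.8,
                              onset_threshold = 0.10,
                              rating_cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                              attraction_match_effect = 1,
                              attraction_pair_sd = 0.6) {
  dvs <- c("rt", "peak_vel", "step", "ipd")
  for (nm in c("subject_sd", "stimulus_sd", "residual_sd")) {
    x <- get(nm)
    if (!all(dvs %in% names(x)) || any(unlist(x[dvs]) <= 0)) {
      aat_abort(sprintf("%s must name positive dispersions for %s",
                        nm, paste(dvs, collapse = ", ")), "bad_params")
    }
  }
  if (length(rating_cutpoints) != 4L || any(diff(rating_cutpoints) <= 0)) {
    aat_abort("rating_cutpoints must be 4 strictly increasing values", "bad_params")
  }
  eff <- c(baseline_log2_rt, direction_effect, attraction_rt_slope,
           attraction_direction_interaction, baseline_step,
           attraction_step_slope, baseline_peak_vel, attraction_vel_slope,
           baseline_ipd, ipd_sex_effect, ipd_orientation_effect,
           ipd_interaction, ipd_attraction_slope)
  if (any(!is.finite(eff))) aat_abort("all effects must be finite", "bad_params")
  if (sway_sd < 0 || step_duration <= 0 || sway_freq_max <= 0) {
    aat_abort("sway_sd must be >= 0; step_duration and sway_freq_max > 0",
              "bad_params")
  }
  structure(as.list(environment())[c(
    "baseline_log2_rt", "direction_effect", "attraction_rt_slope",
    "attraction_direction_interaction", "baseline_step",
    "attraction_step_slope", "baseline_peak_vel", "attraction_vel_slope",
    "baseline_ipd", "ipd_sex_effect", "ipd_orientation_effect",
    "ipd_interaction", "ipd_attraction_slope", "subject_sd", "stimulus_sd",
    "residual_sd", "sway_sd", "sway_freq_max", "step_duration",
    "onset_threshold", "rating_cutpoints", "attraction_match_effect",
    "attraction_pair_sd")],
    class = "generative_params")
}

#' Deterministic bound on simulated sway speed
#'
#' The sway process is a band-limited Gaussian surrogate: per horizontal axis,
#' a sum of `k` sinusoids with random frequencies below `freq_max` and total
#' variance `sway_sd^2`. Its horizontal speed is bounded by
#' `sqrt(2) * sway_sd * 2 * pi * freq_max * sqrt(2 * k)` (each axis
#' contributes at most `sway_sd * sqrt(2/k) * k * 2 * pi * freq_max`).
#'
#' @param sway_sd Sway displacement SD per axis, m.
#' @param freq_max Upper band edge, Hz.
#' @param k Number of sinusoid components per axis.
#' @return Upper bound on sway speed, m/s.
#' @export
sway_speed_bound <- function(sway_sd, freq_max = 0.3, k = 3) {
  sqrt(2) * sway_sd * 2 * pi * freq_max * sqrt(2 * k)
}
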