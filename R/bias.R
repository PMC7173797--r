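#' Approach-bias d-score
#'
#' Standardized bias to approach rather than avoid: the mean of avoidance
#' trials minus the mean of approach trials, divided by the standard
#' deviation of all those trials pooled (sample, n-1 convention). Under this
#' formula a subject who is *faster* to approach (smaller RT) gets a
#' positive RT d-score, while a subject who steps *farther* when approaching
#' gets a negative step-size d-score.
#'
#' @param approach,avoidance Numeric vectors of per-trial values.
#' @return The d-score, or `NA` (with a `reason` attribute) when either
#'   side has fewer than 2 trials or the pooled SD is zero.
#' @export
#' @examples
#' d_score(approach = c(1, 3), avoidance = c(2, 4))
d_score <- function(approach, avoidance) {
  approach <- approach[!is.na(approach)]
  avoidance <- avoidance[!is.na(avoidance)]
  if (length(approach) < 2 || length(avoidance) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 trials per direction"))
  }
  pooled_sd <- sd(c(approach, avoidance))
  if (pooled_sd == 0) {
    return(structure(NA_real_, reason = "zero pooled SD"))
  }
  (mean(avoidance) - mean(approach)) / pooled_sd
}

preferred_sex <- function(orientation) {
  ifelse(orientation == "gynophilic", "female", "male")
}

#' Per-subject approach-bias d-scores
#'
#' Computes [d_score()] per subject for initiation RT, peak velocity and
#' step size, using only post-QC trials toward the subject's preferred
#' avatar sex (female for gynophilic, male for androphilic subjects) and
#' respecting each dependent variable's QC keep flag.
#'
#' @param trials Post-QC AAT trials from [apply_aat_cascade()].
#' @return Tibble `subject_id`, `d_rt`, `d_peak_velocity`, `d_step_size`.
#' @export
d_scores <- function(trials) {
  pref <- trials |>
    filter(.data$avatar_sex == preferred_sex(.data$orientation))
  pref |>
    group_by(.data$subject_id) |>
    summarise(
      d_rt = d_score(.data$rt_ms[.data$direction == "approach" & .data$rt_keep],
                     .data$rt_ms[.data$direction == "avoidance" & .data$rt_keep]),
      d_peak_velocity = d_score(
        .data$peak_velocity[.data$direction == "approach" & .data$peak_velocity_keep],
        .data$peak_velocity[.data$direction == "avoidance" & .data$peak_velocity_keep]),
      d_step_size = d_score(
        .data$step_size[.data$direction == "approach" & .data$step_size_keep],
        .data$step_size[.data$direction == "avoidance" & .data$step_size_keep]),
      .groups = "drop")
}

#' Per-subject IPD aggregates toward the preferred sex
#'
#' Mean stopping distance and mean approach peak velocity per subject over
#' post-QC IPD trials with the subject's preferred avatar sex. Subjects with
#' no eligible trials are absent from the result.
#'
#' @param trials Post-QC IPD trials from [apply_ipd_cascade()].
#' @return Tibble `subject_id`, `mean_ipd`, `mean_peak_velocity`.
#' @export
subject_aggregates <- function(trials) {
  trials |>
    filter(.data$avatar_sex == preferred_sex(.data$orientation)) |>
    group_by(.data$subject_id) |>
    summarise(
      mean_ipd = mean(.data$ipd[.data$ipd_keep]),
      mean_peak_velocity =
        mean(.data$peak_velocity[.data$peak_velocity_keep]),
      .groups = "drop")
}

#' Cross-paradigm correlation table
#'
#' Pearson correlations between subject-level variables (IPD aggregates and
#' AAT d-scores), with pairwise-complete observations. Each correlation gets
#' a pb-style flag from the Fisher-z normal approximation of its posterior:
#' `z ~ Normal(atanh(r), 1/sqrt(n - 3))`, and pb is the percentage of that
#' mass on the far side of zero. Correlations with pb below `flag_below` are
#' starred. Constant columns yield `NA` with a logged reason.
#'
#' @param data Data frame of subject-level variables (one row per subject;
#'   a `subject_id` column, if present, is ignored).
#' @param flag_below pb threshold (percent) for the star flag.
#' @return Tibble `var1`, `var2`, `r`, `n`, `pb`, `flag` covering each
#'   unordered pair once.
#' @export
correlation_table <- function(data, flag_below = 2.5) {
  data <- data[, setdiff(names(data), "subject_id"), drop = FALSE]
  vars <- names(data)
  if (length(vars) < 2) aat_abort("need at least 2 variables", "bad_input")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    x <- data[[p[1]]]; y <- data[[p[2]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 5 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(var1 = p[1], var2 = p[2], r = NA_real_, n = n,
                    pb = NA_real_, flag = FALSE))
    }
    r <- stats::cor(x[ok], y[ok])
    pb <- 100 * stats::pnorm(-abs(atanh(r)) * sqrt(n - 3))
    tibble(var1 = p[1], var2 = p[2], r = r, n = n, pb = pb,
           flag = pb < flag_below)
  })
}
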