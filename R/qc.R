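#' Quality-control configuration
#'
#' Parameters of the trial-exclusion cascade: Tukey fences at
#' `k = 1.5` interquartile ranges beyond the first/third quartile, a 250 ms
#' floor on initiation RT, and a log2 transform of the retained RTs. AAT
#' fences are computed per subject across that subject's remaining trials
#' pooled over the four avatar-sex by direction cells (`aat_grouping =
#' "pooled_within_subject"`; `"per_cell"` computes them within each cell
#' instead); IPD fences are computed per subject and avatar sex.
#'
#' @param tukey_k Fence multiplier on the IQR.
#' @param rt_floor Minimum admissible RT, ms.
#' @param aat_grouping `"pooled_within_subject"` or `"per_cell"`.
#' @param log2_rt Add a `log2_rt` column to the retained trials?
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(tukey_k = 1.5, rt_floor = 250,
                      aat_grouping = c("pooled_within_subject", "per_cell"),
                      log2_rt = TRUE) {
  if (tukey_k <= 0 || rt_floor < 0) {
    aat_abort("tukey_k must be > 0 and rt_floor >= 0", "bad_config")
  }
  structure(list(tukey_k = tukey_k, rt_floor = rt_floor,
                 aat_grouping = match.arg(aat_grouping),
                 log2_rt = isTRUE(log2_rt)),
            class = "qc_config")
}

#' Tukey-fence keep mask
#'
#' Keeps a value iff it lies within `[Q1 - k*IQR, Q3 + k*IQR]`, with
#' quartiles by linear interpolation between order statistics. Fewer than 4
#' finite values: everything is kept (fences are not estimable). `NA` values
#' are kept (they carry no evidence of being outlying).
#'
#' @param values Numeric vector.
#' @param k Fence multiplier.
#' @return Logical keep mask, same length as `values`.
#' @export
#' @examples
#' tukey_mask(c(1:20, 1000))
tukey_mask <- function(values, k = 1.5) {
  if (any(is.infinite(values) | is.nan(values))) {
    aat_abort("non-finite values are not allowed", "bad_values")
  }
  ok <- !is.na(values)
  if (sum(ok) < 4) return(rep(TRUE, length(values)))
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  keep | !ok
}

stage_row <- function(stage, dv, n_before, n_excluded) {
  tibble(stage = stage, dv = dv, n_before = n_before,
         n_excluded = n_excluded,
         pct = 100 * n_excluded / n_before)
}

#' AAT trial-exclusion cascade
#'
#' Applies the exclusion stages in order: (1) drop trials for which no
#' movement could be extracted (`direction_class == "missing"`); (2) drop
#' trials initiated in the wrong direction; (3) per subject and dependent
#' variable, flag Tukey-fence outliers across the subject's remaining trials
#' (pooled over the four avatar-sex by direction cells by default); (4) for
#' RT only, additionally drop trials faster than the RT floor; (5) add a
#' log2 RT column. Stages 3-4 are per-DV: a trial excluded for RT may be
#' retained for step size, so the output carries one keep flag per DV
#' (`rt_keep`, `peak_velocity_keep`, `step_size_keep`) rather than dropping
#' rows. Values are never modified, only flagged.
#'
#' @param trials Extracted AAT trials (from [extract_kinematics()]).
#' @param config A [qc_config()].
#' @return List with `trials` (rows surviving stages 1-2, with per-DV keep
#'   flags and `log2_rt`) and `report` (per-stage exclusion counts and
#'   percentages, each percentage relative to the trials remaining when the
#'   stage ran).
#' @export
apply_aat_cascade <- function(trials, config = qc_config()) {
  stopifnot(all(c("rt_ms", "peak_velocity", "step_size",
                  "direction_class") %in% names(trials)))
  report <- list()
  n0 <- nrow(trials)
  t1 <- filter(trials, .data$direction_class != "missing")
  report[[1]] <- stage_row("unextractable", "all", n0, n0 - nrow(t1))
  t2 <- filter(t1, .data$direction_class == "correct")
  report[[2]] <- stage_row("incorrect_direction", "all", nrow(t1),
                           nrow(t1) - nrow(t2))

  dvs <- c(rt = "rt_ms", peak_velocity = "peak_velocity",
           step_size = "step_size")
  grouping <- if (config$aat_grouping == "pooled_within_subject") {
    list(t2$subject_id)
  } else {
    list(t2$subject_id, t2$avatar_sex, t2$direction)
  }
  for (dv in names(dvs)) {
    v <- t2[[dvs[[dv]]]]
    keep <- unsplit(lapply(split(v, grouping),
                           tukey_mask, k = config$tukey_k), grouping)
    t2[[paste0(dv, "_keep")]] <- keep
    report[[length(report) + 1]] <-
      stage_row("tukey", dv, nrow(t2), sum(!keep))
  }
  floor_drop <- t2$rt_keep & t2$rt_ms < config$rt_floor
  t2$rt_keep <- t2$rt_keep & !floor_drop
  report[[length(report) + 1]] <-
    stage_row("rt_floor", "rt", nrow(t2), sum(floor_drop))
  if (config$log2_rt) t2$log2_rt <- log2(t2$rt_ms)
  list(trials = t2, report = bind_rows(report))
}

#' IPD trial-exclusion cascade
#'
#' Drops trials with no forward movement before the confirm press, then
#' flags Tukey-fence outliers separately for each subject and level of
#' avatar sex, independently for IPD and peak velocity.
#'
#' @param trials Extracted IPD trials.
#' @param config A [qc_config()].
#' @return List with `trials` (keep flags `ipd_keep`,
#'   `peak_velocity_keep`) and `report`.
#' @export
apply_ipd_cascade <- function(trials, config = qc_config()) {
  stopifnot(all(c("ipd", "peak_velocity", "direction_class") %in%
                  names(trials)))
  report <- list()
  n0 <- nrow(trials)
  t1 <- filter(trials, .data$direction_class != "missing")
  report[[1]] <- stage_row("no_forward_movement", "all", n0, n0 - nrow(t1))
  grouping <- list(t1$subject_id, t1$avatar_sex)
  for (dv in c(ipd = "ipd", peak_velocity = "peak_velocity")) {
    keep <- unsplit(lapply(split(t1[[dv]], grouping),
                           tukey_mask, k = config$tukey_k), grouping)
    t1[[paste0(dv, "_keep")]] <- keep
    report[[length(report) + 1]] <-
      stage_row("tukey", dv, nrow(t1), sum(!keep))
  }
  list(trials = t1, report = bind_rows(report))
}
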