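#' Write a cohort to a tracking-log directory
#'
#' Persists a simulated (or otherwise assembled) cohort as plain delimited
#' text: `samples.csv` (trial_id, t, x, y, z; metres/seconds, y vertical,
#' x/z the horizontal plane), a `trials.csv` metadata sidecar, a
#' `ground_truth.csv` table when ground truth is present, and a
#' `log_meta.json` header carrying the format version, sample rate, units
#' and the seed/config of provenance.
#'
#' @param cohort An `aat_cohort` from [simulate_cohort()] (or a list with
#'   `trials`, `samples`, optionally `truth`, `config`).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tracking_log <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  meta <- list(format_version = "1.0",
               units = list(position = "m", time = "s"),
               coordinate_convention = "x,z horizontal; y vertical",
               sample_rate = cohort$config$sample_rate %||% NA,
               seed = cohort$config$seed %||% NA)
  jsonlite::write_json(meta, file.path(dir, "log_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a tracking-log directory
#'
#' Reads and validates a directory written by [write_tracking_log()]:
#' every trajectory row's trial must exist in the metadata sidecar,
#' timestamps must be strictly increasing within each trial (violations are
#' reported with the offending trial and row number), and trials listed in
#' the sidecar with no trajectory rows are surfaced (they will be treated
#' as missing downstream, not dropped silently).
#'
#' @param dir Directory containing `samples.csv`, `trials.csv` and
#'   `log_meta.json`.
#' @return List with `trials`, `samples`, `truth` (NULL if absent), `meta`,
#'   and `empty_trials` (trial ids with no trajectory rows).
#' @export
read_tracking_log <- function(dir) {
  for (f in c("samples.csv", "trials.csv", "log_meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      aat_abort(paste0("tracking log incomplete: missing ", f), "bad_log")
    }
  }
  samples <- as_tibble(utils::read.csv(file.path(dir, "samples.csv")))
  trials <- as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  meta <- jsonlite::read_json(file.path(dir, "log_meta.json"))
  orphans <- setdiff(unique(samples$trial_id), trials$trial_id)
  if (length(orphans) > 0) {
    aat_abort(paste0("trajectory rows with unknown trial_id: ",
                     paste(utils::head(orphans, 5), collapse = ", ")),
              "orphan_trial")
  }
  bad <- samples |>
    group_by(.data$trial_id) |>
    summarise(bad_row = {
      d <- diff(.data$t)
      if (any(d <= 0)) which(d <= 0)[1] + 1L else NA_integer_
    }, .groups = "drop") |>
    filter(!is.na(.data$bad_row))
  if (nrow(bad) > 0) {
    aat_abort(sprintf(
      "non-monotone timestamps in trial %s (sample row %d within trial)",
      bad$trial_id[1], bad$bad_row[1]), "bad_timestamps")
  }
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    as_tibble(utils::read.csv(truth_path))
  }
  list(trials = trials, samples = samples, truth = truth, meta = meta,
       empty_trials = setdiff(trials$trial_id, unique(samples$trial_id)))
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: simulate a cohort (or take one as given), extract
#' kinematics, apply the AAT and IPD quality-control cascades, fit the
#' requested hierarchical models, summarise their posteriors, and compute
#' approach-bias d-scores plus the cross-paradigm correlation table. Every
#' stage is seeded from `seed`, so a rerun with the same arguments
#' reproduces every artifact exactly.
#'
#' @param config A [cohort_config()]; its `seed` is overridden by `seed`.
#' @param params A [generative_params()].
#' @param kin_config A [kinematic_config()].
#' @param qc A [qc_config()].
#' @param profile `"test"` (4 chains x 1000 iterations) or
#'   `"paper_faithful"` (4 x 8000).
#' @param seed Master seed for cohort generation and sampling.
#' @param models Which model families to fit: any of `"aat_implicit"`,
#'   `"aat_explicit"`, `"ipd_implicit"`, `"ipd_explicit"`.
#' @param aat_outcomes AAT outcome columns to model.
#' @param cohort Optional pre-simulated `aat_cohort` (skips simulation).
#' @param out_dir Optional directory; artifacts are written there as
#'   delimited text/JSON with the seed and profile embedded.
#' @return List of class `aat_pipeline` with elements `cohort`,
#'   `aat` (trials + exclusion report), `ipd`, `fits` (named `aat_fit`
#'   objects), `summaries` (tidy effect tables), `r2`, `d_scores`,
#'   `aggregates`, `correlations`, `seed`, `profile`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         params = generative_params(),
                         kin_config = kinematic_config(),
                         qc = qc_config(),
                         profile = c("test", "paper_faithful"),
                         seed = 1L,
                         models = c("aat_implicit", "ipd_implicit"),
                         aat_outcomes = "log2_rt",
                         cohort = NULL,
                         out_dir = NULL) {
  profile <- match.arg(profile)
  models <- match.arg(models, c("aat_implicit", "aat_explicit",
                                "ipd_implicit", "ipd_explicit"),
                      several.ok = TRUE)
  config$seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- simulate_cohort(config, params)

  extracted <- extract_kinematics(cohort$trials, cohort$samples, kin_config)
  aat <- apply_aat_cascade(filter(extracted, .data$experiment == "AAT"), qc)
  ipd <- apply_ipd_cascade(filter(extracted, .data$experiment == "IPD"), qc)

  sampler <- sampler_config(profile = profile, seed = seed)
  fits <- list(); summaries <- list(); r2 <- list()
  for (m in models) {
    if (m %in% c("aat_implicit", "aat_explicit")) {
      for (dv in aat_outcomes) {
        keep_col <- c(log2_rt = "rt_keep", rt_ms = "rt_keep",
                      peak_velocity = "peak_velocity_keep",
                      step_size = "step_size_keep")[[dv]]
        dat <- aat$trials[aat$trials[[keep_col]], ]
        spec <- if (m == "aat_implicit") aat_implicit_spec(dv, sampler)
                else aat_explicit_spec(dv, sampler)
        nm <- paste0(m, "_", dv)
        fits[[nm]] <- fit_model(dat, spec)
        summaries[[nm]] <- summarize_model(fits[[nm]])
        r2[[nm]] <- bayes_r2(fits[[nm]])$summary
      }
    } else {
      dv <- "ipd"
      dat <- ipd$trials[ipd$trials$ipd_keep, ]
      spec <- if (m == "ipd_implicit") ipd_implicit_spec(dv, sampler)
              else ipd_explicit_spec(dv, sampler)
      fits[[m]] <- fit_model(dat, spec)
      summaries[[m]] <- summarize_model(fits[[m]])
      r2[[m]] <- bayes_r2(fits[[m]])$summary
    }
  }

  dsc <- d_scores(aat$trials)
  agg <- subject_aggregates(ipd$trials)
  subject_vars <- agg |>
    left_join(dsc, by = "subject_id")
  correlations <- correlation_table(subject_vars)

  res <- structure(list(cohort = cohort, aat = aat, ipd = ipd,
                        fits = fits, summaries = summaries, r2 = r2,
                        d_scores = dsc, aggregates = agg,
                        subject_vars = subject_vars,
                        correlations = correlations,
                        seed = seed, profile = profile),
                   class = "aat_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write pipeline artifacts as delimited text and JSON
#'
#' @param res An `aat_pipeline` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(res$aat$trials, "aat_trials.csv")
  wcsv(res$aat$report, "aat_exclusions.csv")
  wcsv(res$ipd$trials, "ipd_trials.csv")
  wcsv(res$ipd$report, "ipd_exclusions.csv")
  wcsv(res$d_scores, "d_scores.csv")
  wcsv(res$correlations, "correlations.csv")
  for (nm in names(res$summaries)) {
    wcsv(res$summaries[[nm]], paste0("effects_", nm, ".csv"))
  }
  for (nm in names(res$fits)) {
    dr <- as_tibble(as.data.frame(res$fits[[nm]]$draws))
    dr$chain <- res$fits[[nm]]$chain
    dr$draw <- stats::ave(seq_len(nrow(dr)), dr$chain, FUN = seq_along)
    # population and variance parameters only; group-level draws are bulky
    keepc <- c("chain", "draw",
               grep("^(b\\[|sigma_res|sd_u|cor_u)", names(dr), value = TRUE))
    utils::write.csv(dr[, keepc], file.path(dir, paste0("draws_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = res$seed, profile = res$profile,
         convergence = lapply(res$fits, function(f) {
           list(max_rhat = max(f$rhat$rhat, na.rm = TRUE),
                converged = f$converged)
         })),
    file.path(dir, "run_meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.aat_pipeline <- function(x, ...) {
  cat("<aat_pipeline> seed", x$seed, "profile", x$profile, "\n")
  cat("AAT trials post-QC rows:", nrow(x$aat$trials),
      "| IPD:", nrow(x$ipd$trials), "\n")
  for (nm in names(x$summaries)) {
    cat("--", nm, "--\n")
    print(x$summaries[[nm]])
  }
  invisible(x)
}
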