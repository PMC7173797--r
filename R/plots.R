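#' Velocity-profile plot for one trial
#'
#' Smoothed horizontal speed over time with the onset threshold, detected
#' onset and movement interval marked — the per-trial picture behind the
#' kinematic parameter extraction.
#'
#' @param samples One trial's trajectory (`t`, `x`, `y`, `z`).
#' @param config A [kinematic_config()].
#' @param stimulus_onset Stimulus-onset time, s.
#' @return A ggplot object.
#' @export
plot_velocity_profile <- function(samples, config = kinematic_config(),
                                  stimulus_onset = 0) {
  sm <- smooth_trajectory(resample_uniform(samples, config$resample_rate),
                          config)
  spd <- compute_speed(sm)
  det <- detect_onset(spd, sm$t, stimulus_onset, config)
  df <- tibble(t = sm$t, speed = spd)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = config$onset_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time since stimulus onset (s)", y = "speed (m/s)")
  if (!is.na(det$onset)) {
    p <- p + ggplot2::geom_vline(xintercept = det$onset, colour = "red")
  }
  p
}

#' Posterior density plot with HDI and opposite-sign shading
#'
#' One density per effect, with the 95% HDI bar, the posterior median, and
#' the posterior mass on the far side of zero shaded dark red — a visual
#' rendering of the posterior median p-value.
#'
#' @param fit An `aat_fit`, or a named list of draw vectors.
#' @param terms Which population terms to show (default all but the
#'   intercept).
#' @return A ggplot object.
#' @export
plot_posterior_density <- function(fit, terms = NULL) {
  draws <- if (inherits(fit, "aat_fit")) {
    b <- population_draws(fit)
    as.list(as.data.frame(b[, setdiff(colnames(b), "(Intercept)"),
                            drop = FALSE]))
  } else fit
  if (!is.null(terms)) draws <- draws[terms]
  df <- purrr::imap_dfr(draws, function(d, nm) {
    tibble(term = nm, value = d,
           opposite = sign(d) != sign(median(d)) | d == 0)
  })
  hdis <- purrr::imap_dfr(draws, function(d, nm) {
    h <- hdi95(d)
    tibble(term = nm, lower = h[["lower"]], upper = h[["upper"]],
           med = median(d))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(fill = .data$opposite),
                            bins = 60, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(data = hdis,
                            ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper, y = 0),
                            inherit.aes = FALSE, height = 0) +
    ggplot2::geom_point(data = hdis,
                        ggplot2::aes(x = .data$med, y = 0),
                        inherit.aes = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black",
                                          `TRUE` = "darkred")) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "effect (outcome units)", y = NULL)
}

#' Cell-mean plot of a dependent variable
#'
#' Mean and standard error of a per-trial dependent variable by sexual
#' orientation, avatar sex, and (for AAT data) reaction direction.
#'
#' @param trials Post-QC trial tibble.
#' @param dv Column to summarise.
#' @param keep Optional name of the QC keep-flag column to respect.
#' @return A ggplot object.
#' @export
plot_cell_means <- function(trials, dv, keep = NULL) {
  if (!is.null(keep)) trials <- trials[trials[[keep]], ]
  has_dir <- "direction" %in% names(trials) &&
    !all(is.na(trials$direction))
  grp <- c("orientation", "avatar_sex", if (has_dir) "direction")
  df <- trials |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(m = mean(.data[[dv]], na.rm = TRUE),
              se = sd(.data[[dv]], na.rm = TRUE) /
                sqrt(sum(!is.na(.data[[dv]]))),
              .groups = "drop")
  aes <- if (has_dir) {
    ggplot2::aes(x = .data$avatar_sex, y = .data$m,
                 colour = .data$direction, group = .data$direction)
  } else {
    ggplot2::aes(x = .data$avatar_sex, y = .data$m, group = 1)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           width = 0.1,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::facet_wrap(~orientation) +
    ggplot2::labs(x = "avatar sex", y = dv)
}

#' @method autoplot aat_fit
#' @export
#' @importFrom ggplot2 autoplot
autoplot.aat_fit <- function(object, ...) plot_posterior_density(object, ...)
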