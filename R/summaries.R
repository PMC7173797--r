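#' Posterior median p-value
#'
#' Percentage of posterior draws that are zero or of sign opposite to the
#' posterior median — the probability, given the data, that the effect is
#' null or points the other way. By convention, draws exactly at zero count
#' against the effect, and a median of exactly zero yields 50%.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' pb_value(c(-1, 2, 3, 4)) # 25
pb_value <- function(draws) {
  if (length(draws) == 0) aat_abort("no draws", "empty_draws")
  med <- median(draws)
  if (med == 0) return(50)
  s <- sign(med)
  100 * sum(draws == 0 | sign(draws) == -s) / length(draws)
}

#' Highest-density interval
#'
#' Shortest contiguous interval containing at least `prob` of the draws,
#' found by scanning all windows of the required length over the sorted
#' draws.
#'
#' @param draws Numeric vector of posterior draws (at least 20 for a
#'   meaningful 95% interval).
#' @param prob Coverage probability.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi95 <- function(draws, prob = 0.95) {
  n <- length(draws)
  if (n == 0) aat_abort("no draws", "empty_draws")
  s <- sort(draws)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m])
}

#' Standardized effect draws (delta_t)
#'
#' Divides each coefficient draw by the total outcome scale — the square
#' root of the sum of all varying-effect variances plus the residual
#' variance for that draw — yielding a Cohen's-d-like standardized effect
#' for mixed models.
#'
#' @param b_draws Coefficient draws.
#' @param variance_draws Matrix (draws x components) of variance-component
#'   draws (varying-effect variances and residual variance), aligned with
#'   `b_draws`.
#' @return Vector of standardized-effect draws.
#' @export
delta_t <- function(b_draws, variance_draws) {
  variance_draws <- as.matrix(variance_draws)
  if (nrow(variance_draws) != length(b_draws)) {
    aat_abort("variance draws not aligned with coefficient draws",
              "misaligned")
  }
  tot <- rowSums(variance_draws)
  if (any(tot <= 0)) aat_abort("non-positive total variance", "bad_variance")
  b_draws / sqrt(tot)
}

#' Summarise one set of effect draws
#'
#' @param draws Numeric vector of posterior draws.
#' @param label Parameter label.
#' @param delta_draws Optional standardized-effect draws for the same
#'   parameter.
#' @return One-row tibble with the posterior median, 95% HDI bounds, pb
#'   value, and (if given) standardized-effect median and HDI.
#' @export
summarise_effect <- function(draws, label = "effect", delta_draws = NULL) {
  h <- hdi95(draws)
  out <- tibble(term = label, estimate = median(draws),
                conf.low = h[["lower"]], conf.high = h[["upper"]],
                pb = pb_value(draws))
  if (!is.null(delta_draws)) {
    hd <- hdi95(delta_draws)
    out$delta_t <- median(delta_draws)
    out$delta_t.low <- hd[["lower"]]
    out$delta_t.high <- hd[["upper"]]
  }
  out
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted values (population effects
#' plus all varying effects) divided by itself plus the residual variance.
#'
#' @param fit An `aat_fit` from [fit_model()].
#' @param chunk Draws processed per block of matrix work.
#' @return List with `draws` (R-squared per posterior draw) and `summary`
#'   (one-row tibble: median and 95% HDI).
#' @export
bayes_r2 <- function(fit, chunk = 500) {
  des <- fit$design
  b_idx <- match(paste0("b[", seq_along(des$terms), "]"),
                 colnames(fit$draws))
  sig <- fit$draws[, "sigma_res"]
  nd <- nrow(fit$draws)
  # precompute sparse-style ranef expansion: fitted = X b + sum_g A_g u_g
  A <- list(); u_idx <- list()
  for (g in seq_along(des$blocks)) {
    bl <- des$blocks[[g]]
    J <- bl$n_groups; K <- ncol(bl$Z)
    cols <- character(J * K)
    Am <- matrix(0, nrow(des$X), J * K)
    for (k in seq_len(K)) {
      Am[cbind(seq_len(nrow(des$X)), (k - 1) * J + bl$index)] <- bl$Z[, k]
      cols[(k - 1) * J + seq_len(J)] <-
        paste0("u", g, "[", seq_len(J), ",", k, "]")
    }
    idx <- match(cols, colnames(fit$draws))
    if (anyNA(idx)) aat_abort("varying-effect draws not found", "misaligned")
    A[[g]] <- Am; u_idx[[g]] <- idx
  }
  r2 <- numeric(nd)
  for (start in seq(1, nd, by = chunk)) {
    sel <- start:min(start + chunk - 1, nd)
    f <- des$X %*% t(fit$draws[sel, b_idx, drop = FALSE])
    for (g in seq_along(A)) {
      f <- f + A[[g]] %*% t(fit$draws[sel, u_idx[[g]], drop = FALSE])
    }
    vf <- apply(f, 2, var)
    r2[sel] <- vf / (vf + sig[sel]^2)
  }
  list(draws = r2, summary = summarise_effect(r2, "bayes_r2"))
}

#' Posterior contrast over population effects
#'
#' Forms the linear combination of population-effect draws given by
#' `weights` (named by model term) and summarises it with the posterior
#' median, 95% HDI and pb value.
#'
#' @param fit An `aat_fit`.
#' @param weights Named numeric vector; names must be population terms of
#'   the model. Unnamed terms get weight 0.
#' @param label Label for the output row.
#' @return One-row tibble (see [summarise_effect()]).
#' @export
posterior_contrast <- function(fit, weights, label = "contrast") {
  terms <- fit$design$terms
  bad <- setdiff(names(weights), terms)
  if (length(bad) > 0) {
    aat_abort(paste0("unknown terms in contrast: ",
                     paste(bad, collapse = ", ")), "bad_contrast")
  }
  w <- setNames(numeric(length(terms)), terms)
  w[names(weights)] <- weights
  b <- fit$draws[, paste0("b[", seq_along(terms), "]"), drop = FALSE]
  summarise_effect(drop(b %*% w), label)
}

#' Approach-bias contrasts per design cell
#'
#' For a fully crossed orientation x avatar-sex x direction model, computes
#' the posterior approach-minus-avoidance difference within each
#' orientation by avatar-sex cell: the direction main effect plus the
#' relevant interaction terms weighted by the cell's codes.
#'
#' @param fit An `aat_fit` of the implicit AAT model.
#' @return Tibble with one row per orientation x avatar-sex cell.
#' @export
approach_bias_contrasts <- function(fit) {
  cells <- tidyr::crossing(orientation = c("gynophilic", "androphilic"),
                           avatar_sex = c("male", "female"))
  purrr::pmap_dfr(cells, function(orientation, avatar_sex) {
    o <- code_orientation(orientation)
    s <- code_avatar_sex(avatar_sex)
    w <- c(direction = 1,
           "orientation:direction" = o,
           "avatar_sex:direction" = s,
           "orientation:avatar_sex:direction" = o * s)
    w <- w[names(w) %in% fit$design$terms]
    posterior_contrast(fit, w,
                       label = paste(orientation, avatar_sex, sep = ":")) |>
      mutate(orientation = orientation, avatar_sex = avatar_sex,
             .before = 1)
  })
}
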