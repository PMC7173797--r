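#' Default effect coding for the design factors
#'
#' Factors are effect-coded at +/-0.5 so each coefficient is the difference
#' between the two cell means of its factor: gynophilic -0.5 / androphilic
#' +0.5; female +0.5 / male -0.5; approach +0.5 / avoidance -0.5.
#'
#' @return Named list of level-to-code maps.
#' @export
default_coding <- function() {
  list(orientation = c(gynophilic = -0.5, androphilic = 0.5),
       avatar_sex = c(female = 0.5, male = -0.5),
       direction = c(approach = 0.5, avoidance = -0.5))
}

#' Varying-effects block
#'
#' One grouping unit of the hierarchical model (e.g. subjects, stimuli)
#' with a varying intercept and/or varying slopes. When `correlated = TRUE`
#' (and the block has more than one term) the block's effects get a joint
#' covariance with a weakly informative prior on the correlation matrix.
#'
#' @param group Name of the grouping column.
#' @param intercept Include a varying intercept?
#' @param slopes Character vector of slope terms (population term names;
#'   interactions as `"a:b"`).
#' @param correlated Model correlations among the block's effects?
#' @return A list of class `varying_block`.
#' @export
varying_block <- function(group, intercept = TRUE, slopes = character(),
                          correlated = TRUE) {
  structure(list(group = group, intercept = isTRUE(intercept),
                 slopes = slopes, correlated = isTRUE(correlated)),
            class = "varying_block")
}

#' Prior configuration
#'
#' Weakly informative priors in the style standard for Bayesian mixed
#' models: Normal(0, 1) on population effects, Student-t(3, 0, 1) on the
#' intercept (thicker tails), half-t(3, 0, 1) on all scale parameters, all
#' rescaled by the outcome's mean/SD when `scale_to_outcome` (the default),
#' so the priors adapt to the unit of each dependent variable. Correlation
#' matrices of varying-effect blocks get the scaled inverse-Wishart prior
#' (near-uniform marginal correlations).
#'
#' @param population_sd Prior SD of population effects (in outcome SD units
#'   when `scale_to_outcome`).
#' @param intercept_df Student-t degrees of freedom for the intercept prior.
#' @param scale_to_outcome Rescale prior scales by `sd(y)` and centre the
#'   intercept prior at `mean(y)`?
#' @param intercept_prior `"student_t"` or `"normal"`.
#' @param sigma_fixed Optional known residual SD; when given, the residual
#'   scale is fixed rather than estimated.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(population_sd = 1, intercept_df = 3,
                       scale_to_outcome = TRUE,
                       intercept_prior = c("student_t", "normal"),
                       sigma_fixed = NULL) {
  structure(list(population_sd = population_sd,
                 intercept_df = intercept_df,
                 scale_to_outcome = isTRUE(scale_to_outcome),
                 intercept_prior = match.arg(intercept_prior),
                 sigma_fixed = sigma_fixed),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param chains Number of MCMC chains.
#' @param iterations Iterations per chain, including warm-up.
#' @param warmup_frac Fraction of iterations used for adaptation/burn-in.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param profile Convenience presets: `"paper_faithful"` (4 chains x 8000,
#'   10% warm-up) or `"test"` (4 x 1000, 10% warm-up).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = 8000,
                           warmup_frac = 0.10, seed = 1L,
                           profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("test", "paper_faithful"))
    iterations <- if (profile == "test") 1000 else 8000
    chains <- 4; warmup_frac <- 0.10
  }
  stopifnot(chains >= 1, iterations >= 20, warmup_frac > 0, warmup_frac < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_frac = warmup_frac, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Hierarchical linear mixed-model specification
#'
#' Declarative description of one Bayesian LMM: the outcome column, the
#' population-level variables (effect-coded factors and/or covariates,
#' fully crossed into all interactions by default), the varying-effect
#' blocks, priors and sampler settings.
#'
#' @param outcome Outcome column name.
#' @param population Factor names entering the population level.
#' @param covariates Numeric covariate names entering the population level.
#' @param coding Level-to-code maps for the factors (see [default_coding()]).
#' @param covariate_transform Named list mapping covariate name to one of
#'   `"raw"`, `"center"` (subtract the mean), `"midpoint"` (subtract the
#'   rating-scale midpoint 3) or `"standardize"`.
#' @param full_crossing Include all interactions among population variables?
#' @param varying List of [varying_block()]s.
#' @param priors A [prior_spec()].
#' @param sampler A [sampler_config()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome, population = character(),
                       covariates = character(),
                       coding = default_coding(),
                       covariate_transform = list(),
                       full_crossing = TRUE,
                       varying = list(),
                       priors = prior_spec(),
                       sampler = sampler_config()) {
  for (f in population) {
    if (is.null(coding[[f]])) {
      aat_abort(paste0("no coding map for factor ", f), "bad_spec")
    }
  }
  structure(list(outcome = outcome, population = population,
                 covariates = covariates, coding = coding,
                 covariate_transform = covariate_transform,
                 full_crossing = isTRUE(full_crossing),
                 varying = varying, priors = priors, sampler = sampler),
            class = "model_spec")
}

# all non-empty subsets of vars, mains first, as "a:b" labels
crossing_terms <- function(vars, full = TRUE) {
  if (!full || length(vars) <= 1) return(as.list(vars))
  out <- list()
  for (k in seq_along(vars)) {
    out <- c(out, utils::combn(vars, k, simplify = FALSE))
  }
  out
}

#' Preset model specifications
#'
#' The four models of the analysis: the implicit AAT model (orientation x
#' avatar sex x reaction direction, fully crossed; varying intercept plus
#' crossed avatar-sex and direction slopes per subject, varying intercept
#' plus direction slope per avatar), the explicit AAT model (reaction
#' direction x per-trial attractiveness rating centred at the scale
#' midpoint; varying intercept and direction slope per subject and per
#' stimulus), the implicit IPD model (orientation x avatar sex; varying
#' intercept plus avatar-sex slope per subject, varying intercept per
#' stimulus — avatar sex is constant within a stimulus, so a stimulus-level
#' sex slope is not identifiable), and the explicit IPD model (standardized
#' attractiveness x avatar sex; varying intercept plus avatar-sex slope per
#' subject, varying intercept per stimulus).
#'
#' @param outcome Outcome column (`"log2_rt"`, `"peak_velocity"`,
#'   `"step_size"` or `"ipd"`).
#' @param sampler A [sampler_config()].
#' @return A [model_spec()].
#' @name preset_specs
NULL

#' @rdname preset_specs
#' @export
aat_implicit_spec <- function(outcome = "log2_rt",
                              sampler = sampler_config()) {
  model_spec(outcome,
             population = c("orientation", "avatar_sex", "direction"),
             varying = list(
               varying_block("subject_id", TRUE,
                             c("avatar_sex", "direction",
                               "avatar_sex:direction")),
               varying_block("avatar_id", TRUE, "direction")),
             sampler = sampler)
}

#' @rdname preset_specs
#' @export
aat_explicit_spec <- function(outcome = "log2_rt",
                              sampler = sampler_config()) {
  model_spec(outcome,
             population = "direction",
             covariates = "rating",
             covariate_transform = list(rating = "midpoint"),
             varying = list(
               varying_block("subject_id", TRUE, "direction"),
               varying_block("avatar_id", TRUE, "direction")),
             sampler = sampler)
}

#' @rdname preset_specs
#' @export
ipd_implicit_spec <- function(outcome = "ipd",
                              sampler = sampler_config()) {
  model_spec(outcome,
             population = c("orientation", "avatar_sex"),
             varying = list(
               varying_block("subject_id", TRUE, "avatar_sex"),
               varying_block("avatar_id", TRUE)),
             sampler = sampler)
}

#' @rdname preset_specs
#' @export
ipd_explicit_spec <- function(outcome = "ipd",
                              sampler = sampler_config()) {
  model_spec(outcome,
             population = "avatar_sex",
             covariates = "rating",
             covariate_transform = list(rating = "standardize"),
             varying = list(
               varying_block("subject_id", TRUE, "avatar_sex"),
               varying_block("avatar_id", TRUE)),
             sampler = sampler)
}

code_column <- function(data, var, spec) {
  if (var %in% spec$population) {
    map <- spec$coding[[var]]
    vals <- data[[var]]
    bad <- setdiff(unique(vals), names(map))
    if (length(bad) > 0) {
      aat_abort(paste0("unseen level(s) in ", var, ": ",
                       paste(bad, collapse = ", ")), "bad_level")
    }
    unname(map[vals])
  } else {
    x <- data[[var]]
    tr <- spec$covariate_transform[[var]] %||% "raw"
    switch(tr,
           raw = x,
           center = x - mean(x),
           midpoint = x - 3,
           standardize = (x - mean(x)) / sd(x),
           aat_abort(paste0("unknown covariate transform: ", tr),
                     "bad_spec"))
  }
}

#' Build design matrices for a model specification
#'
#' Produces the population design matrix (intercept, effect-coded main
#' effects, and — with full crossing — all interaction products) and, per
#' varying block, the within-block design columns and group indices.
#'
#' @param data Analysis-ready trial table.
#' @param spec A [model_spec()].
#' @return List with `y`, `X` (N x P), `terms` (column labels, first
#'   `"(Intercept)"`), and `blocks` (each with `Z`, `labels`, `index`,
#'   `levels`, `n_groups`, `correlated`, `group`).
#' @export
build_design <- function(data, spec) {
  vars <- c(spec$population, spec$covariates)
  need <- c(spec$outcome, vars, vapply(spec$varying, `[[`, "", "group"))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    aat_abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
              "bad_data")
  }
  y <- data[[spec$outcome]]
  if (anyNA(y)) aat_abort("outcome contains missing values", "bad_data")
  cols <- lapply(setNames(vars, vars), code_column, data = data, spec = spec)
  term_sets <- crossing_terms(vars, spec$full_crossing)
  X <- cbind(1, vapply(term_sets,
                       function(ts) Reduce(`*`, cols[ts]),
                       numeric(nrow(data))))
  terms <- c("(Intercept)",
             vapply(term_sets, paste, "", collapse = ":"))
  colnames(X) <- terms

  blocks <- lapply(spec$varying, function(bl) {
    zcols <- list()
    labels <- character()
    if (bl$intercept) { zcols <- list(rep(1, nrow(data))); labels <- "(Intercept)" }
    for (sl in bl$slopes) {
      parts <- strsplit(sl, ":", fixed = TRUE)[[1]]
      bad <- setdiff(parts, vars)
      if (length(bad) > 0) {
        aat_abort(paste0("varying slope term not in population terms: ", sl),
                  "bad_spec")
      }
      zcols <- c(zcols, list(Reduce(`*`, cols[parts])))
      labels <- c(labels, sl)
    }
    gvals <- data[[bl$group]]
    levels <- sort(unique(gvals))
    list(group = bl$group, Z = do.call(cbind, zcols), labels = labels,
         index = match(gvals, levels), levels = levels,
         n_groups = length(levels), correlated = bl$correlated)
  })
  list(y = y, X = X, terms = terms, blocks = blocks)
}

# compose the JAGS model string for a design
jags_code <- function(design, priors) {
  nb <- length(design$blocks)
  re <- if (nb > 0) paste0(" + ", paste0("re", seq_len(nb), "[i]",
                                         collapse = " + ")) else ""
  lines <- c("model {",
             "  for (i in 1:N) {",
             "    y[i] ~ dnorm(mu[i], prec_res)",
             paste0("    mu[i] <- inprod(X[i,], b[])", re))
  for (g in seq_len(nb)) {
    K <- ncol(design$blocks[[g]]$Z)
    lines <- c(lines, if (K == 1) {
      sprintf("    re%d[i] <- Z%d[i,1] * u%d[g%d[i],1]", g, g, g, g)
    } else {
      sprintf("    re%d[i] <- inprod(Z%d[i,], u%d[g%d[i],])", g, g, g, g)
    })
  }
  lines <- c(lines, "  }")
  intercept <- if (priors$intercept_prior == "student_t") {
    sprintf("  b[1] ~ dt(mean_y, prec_scale, %d)", priors$intercept_df)
  } else {
    "  b[1] ~ dnorm(mean_y, prec_scale)"
  }
  lines <- c(lines, intercept)
  if (ncol(design$X) > 1) {
    lines <- c(lines,
               sprintf("  for (p in 2:%d) { b[p] ~ dnorm(0, prec_scale) }",
                       ncol(design$X)))
  }
  for (g in seq_len(nb)) {
    bl <- design$blocks[[g]]
    K <- ncol(bl$Z); J <- bl$n_groups
    if (K == 1) {
      lines <- c(lines,
        sprintf("  for (j in 1:%d) { u%d[j,1] ~ dnorm(0, pow(sd_u%d[1], -2)) }",
                J, g, g),
        sprintf("  sd_u%d[1] ~ dt(0, prec_scale, 3) T(0,)", g))
    } else if (bl$correlated) {
      # scaled inverse-Wishart: u = xi * e, e ~ MVN(0, inverse(Om))
      lines <- c(lines,
        sprintf("  for (j in 1:%d) { e%d[j,1:%d] ~ dmnorm(zero%d[], Om%d[,]) }",
                J, g, K, g, g),
        sprintf("  Om%d[1:%d,1:%d] ~ dwish(R%d[,], %d)", g, K, K, g, K + 1),
        sprintf("  S%d[1:%d,1:%d] <- inverse(Om%d[,])", g, K, K, g),
        sprintf("  for (k in 1:%d) {", K),
        sprintf("    xi%d[k] ~ dt(0, prec_scale, 3) T(0,)", g),
        sprintf("    sd_u%d[k] <- xi%d[k] * sqrt(S%d[k,k])", g, g, g),
        sprintf("    for (j in 1:%d) { u%d[j,k] <- xi%d[k] * e%d[j,k] }",
                J, g, g, g),
        "  }",
        sprintf("  for (k in 1:%d) { for (l in 1:%d) {", K, K),
        sprintf("    cor_u%d[k,l] <- S%d[k,l] / sqrt(S%d[k,k] * S%d[l,l])",
                g, g, g, g),
        "  } }")
    } else {
      lines <- c(lines,
        sprintf("  for (k in 1:%d) {", K),
        sprintf("    sd_u%d[k] ~ dt(0, prec_scale, 3) T(0,)", g),
        sprintf("    for (j in 1:%d) { u%d[j,k] ~ dnorm(0, pow(sd_u%d[k], -2)) }",
                J, g, g),
        "  }")
    }
  }
  if (is.null(priors$sigma_fixed)) {
    lines <- c(lines,
               "  sigma_res ~ dt(0, prec_scale, 3) T(0,)",
               "  prec_res <- pow(sigma_res, -2)")
  } else {
    lines <- c(lines,
               "  sigma_res <- sigma_fixed",
               "  prec_res <- pow(sigma_fixed, -2)")
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit a Bayesian hierarchical linear mixed model
#'
#' Builds the design from `data` and `spec` and samples the posterior with
#' JAGS (Gibbs sampling), using the priors and sampler settings declared in
#' `spec`.
#' The first 'warm-up' fraction of iterations is spent on sampler
#' adaptation and burn-in and discarded. Convergence is assessed with
#' split-R-hat on every monitored parameter; a fit with any R-hat at or
#' above 1.1 is flagged (`converged = FALSE`), never silently accepted.
#'
#' @param data Analysis-ready trial table (post-QC, complete rows for the
#'   modelled columns).
#' @param spec A [model_spec()].
#' @param quiet Suppress JAGS progress output?
#' @return An object of class `aat_fit`: posterior draw matrix (rows =
#'   draws across chains, labelled columns), chain index, design, spec,
#'   per-parameter R-hat table and convergence flag.
#' @export
fit_model <- function(data, spec, quiet = TRUE) {
  # block-updating sampler for linear models: much better mixing of the
  # intercept / varying-intercept pair than single-site Gibbs
  rjags::load.module("glm", quiet = TRUE)
  design <- build_design(data, spec)
  priors <- spec$priors
  y <- design$y
  if (priors$scale_to_outcome) {
    mean_y <- mean(y); sd_scale <- sd(y) * priors$population_sd
  } else {
    mean_y <- 0; sd_scale <- priors$population_sd
  }
  dat <- list(N = length(y), y = y, X = design$X,
              mean_y = mean_y, prec_scale = 1 / sd_scale^2)
  monitors <- c("b", "sigma_res")
  for (g in seq_along(design$blocks)) {
    bl <- design$blocks[[g]]
    K <- ncol(bl$Z)
    dat[[paste0("Z", g)]] <- bl$Z
    dat[[paste0("g", g)]] <- bl$index
    monitors <- c(monitors, paste0("sd_u", g), paste0("u", g))
    if (K > 1 && bl$correlated) {
      dat[[paste0("zero", g)]] <- rep(0, K)
      dat[[paste0("R", g)]] <- diag(K)
      monitors <- c(monitors, paste0("cor_u", g))
    }
  }
  if (!is.null(priors$sigma_fixed)) dat$sigma_fixed <- priors$sigma_fixed

  sam <- spec$sampler
  warmup <- max(2L, floor(sam$iterations * sam$warmup_frac))
  keep <- sam$iterations - warmup
  inits <- lapply(seq_len(sam$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sam$seed + c)
  })
  code <- jags_code(design, priors)
  run_jags <- function() {
    jm <- rjags::jags.model(textConnection(code), data = dat,
                            inits = inits, n.chains = sam$chains,
                            n.adapt = ceiling(warmup / 2), quiet = quiet)
    stats::update(jm, warmup - ceiling(warmup / 2),
                  progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = keep,
                        progress.bar = "none")
  }
  mcmc <- if (quiet) {
    # load.module messages etc. are noise in pipelines
    suppressWarnings(run_jags())
  } else run_jags()

  draws <- do.call(rbind, lapply(mcmc, as.matrix))
  chain <- rep(seq_len(sam$chains), each = keep)
  # normalise K = 1 varying-effect names to u<g>[j,1]
  cn <- colnames(draws)
  cn[cn == "b"] <- "b[1]"
  fix <- grepl("^u[0-9]+\\[[0-9]+\\]$", cn)
  cn[fix] <- sub("\\]$", ",1]", cn[fix])
  fix_sd <- grepl("^sd_u[0-9]+$", cn)
  cn[fix_sd] <- paste0(cn[fix_sd], "[1]")
  colnames(draws) <- cn

  fit <- structure(list(draws = draws, chain = chain, spec = spec,
                        design = design, mcmc_dim = c(keep, sam$chains),
                        divergences = 0L),
                   class = "aat_fit")
  conv <- check_convergence(fit)
  fit$rhat <- conv
  fit$converged <- all(conv$rhat < 1.1, na.rm = TRUE)
  fit
}

split_rhat_one <- function(x) {
  # x: iterations x chains; split each chain in half
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-R-hat convergence diagnostics
#'
#' Potential-scale-reduction factor computed on split chains (each chain's
#' first and second halves treated as separate sequences), per monitored
#' parameter. Values near 1 indicate convergence; the accepted threshold is
#' 1.1.
#'
#' @param fit An `aat_fit`.
#' @return Tibble `parameter`, `rhat`, sorted by decreasing R-hat, with the
#'   overall pass/fail as attribute `pass`.
#' @export
check_convergence <- function(fit) {
  keep <- fit$mcmc_dim[1]; chains <- fit$mcmc_dim[2]
  if (chains < 2) aat_abort("need at least 2 chains for R-hat", "bad_chains")
  rhats <- vapply(colnames(fit$draws), function(p) {
    split_rhat_one(matrix(fit$draws[, p], nrow = keep, ncol = chains))
  }, numeric(1))
  out <- tibble(parameter = names(rhats), rhat = unname(rhats)) |>
    arrange(dplyr::desc(.data$rhat))
  attr(out, "pass") <- all(out$rhat < 1.1, na.rm = TRUE)
  out
}

# draws of all variance components (varying-effect variances + residual)
variance_component_draws <- function(fit) {
  cn <- colnames(fit$draws)
  sds <- cn[grepl("^sd_u", cn)]
  cbind(fit$draws[, sds, drop = FALSE]^2,
        sigma2 = fit$draws[, "sigma_res"]^2)
}

#' Population-effect draws of a fitted model
#'
#' @param fit An `aat_fit`.
#' @return Matrix of draws with one labelled column per population term.
#' @export
population_draws <- function(fit) {
  b <- fit$draws[, paste0("b[", seq_along(fit$design$terms), "]"),
                 drop = FALSE]
  colnames(b) <- fit$design$terms
  b
}

#' Posterior effect summaries of a fitted model
#'
#' One row per population-level term: posterior median, 95% HDI, posterior
#' median p-value, and the standardized effect size (coefficient draws
#' divided by the total outcome scale).
#'
#' @param fit An `aat_fit`.
#' @return Tibble of effect summaries.
#' @export
summarize_model <- function(fit) {
  b <- population_draws(fit)
  vc <- variance_component_draws(fit)
  purrr::map_dfr(colnames(b), function(tm) {
    summarise_effect(b[, tm], tm, delta_draws = delta_t(b[, tm], vc))
  })
}

#' @method tidy aat_fit
#' @export
tidy.aat_fit <- function(x, ...) summarize_model(x)

#' @method glance aat_fit
#' @export
glance.aat_fit <- function(x, ...) {
  tibble(outcome = x$spec$outcome,
         nobs = nrow(x$design$X),
         ndraws = nrow(x$draws),
         chains = x$mcmc_dim[2],
         sigma = median(x$draws[, "sigma_res"]),
         max_rhat = max(x$rhat$rhat, na.rm = TRUE),
         converged = x$converged,
         divergences = x$divergences)
}

#' @export
print.aat_fit <- function(x, ...) {
  cat("<aat_fit>", x$spec$outcome, "~",
      paste(setdiff(x$design$terms, "(Intercept)"), collapse = " + "), "\n")
  cat("  ", nrow(x$draws), "posterior draws,", x$mcmc_dim[2], "chains;",
      "max split-R-hat", round(max(x$rhat$rhat, na.rm = TRUE), 3),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(summarize_model(x))
  invisible(x)
}
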