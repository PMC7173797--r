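# Independent brute-force oracles used across the suite. These are written
# as literal transcriptions of each definition, deliberately unshared with
# the package implementations.

# least-squares polynomial fit over one centred window, evaluated at centre
oracle_sg_point <- function(v, i, window, order) {
  half <- (window - 1) %/% 2
  idx <- (i - half):(i + half)
  tt <- idx - i
  fit <- stats::lm(v[idx] ~ poly(tt, order, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(tt = 0)))
}

# linear scan for the first sustained threshold crossing
oracle_onset <- function(speed, t, threshold, sustain) {
  n <- length(speed)
  for (i in seq_len(n - sustain + 1)) {
    if (all(speed[i:(i + sustain - 1)] > threshold)) return(t[i])
  }
  NA_real_
}

# quartiles by hand via the linear-interpolation rule, then fences
oracle_tukey_keep <- function(v, k = 1.5) {
  qs <- function(p) {
    s <- sort(v)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- qs(0.25); q3 <- qs(0.75); iqr <- q3 - q1
  v >= q1 - k * iqr & v <= q3 + k * iqr
}

# exhaustive shortest-window HDI over the sorted draws
oracle_hdi <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (i in 1:(n - m)) {
    w <- s[i + m] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m])
  }
  best[2:3]
}

# split-R-hat from the definition, one parameter, draws matrix iter x chains
oracle_split_rhat <- function(x) {
  n <- nrow(x) %/% 2
  seqs <- list()
  for (c in seq_len(ncol(x))) {
    seqs <- c(seqs, list(x[1:n, c], x[(n + 1):(2 * n), c]))
  }
  m <- length(seqs)
  means <- sapply(seqs, mean)
  W <- mean(sapply(seqs, var))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# tiny deterministic AAT trial table with known composition for QC tests
qc_fixture <- function() {
  tibble::tibble(
    trial_id = sprintf("T%02d", 1:12),
    subject_id = "S001",
    orientation = "gynophilic",
    avatar_sex = rep(c("female", "male"), 6),
    direction = rep(c("approach", "avoidance"), each = 6),
    rt_ms = c(500, 520, 480, 510, 490, 10000, 530, 505, 515, 495, 502, 498),
    peak_velocity = c(rep(0.9, 11), 0.88),
    step_size = c(rep(50, 11), 51),
    direction_class = c(rep("correct", 10), "incorrect", "missing")
  )
}

# simulate directly from the fully crossed implicit LMM with known truth
simulate_implicit_lmm <- function(n_sub = 24, n_av = 20, trials_per_sub = 20,
                                  beta = c(`(Intercept)` = 9.2,
                                           orientation = 0.05,
                                           avatar_sex = -0.03,
                                           direction = -0.10,
                                           `orientation:avatar_sex` = -0.06,
                                           `orientation:direction` = 0.02,
                                           `avatar_sex:direction` = 0.03,
                                           `orientation:avatar_sex:direction` = 0.22),
                                  sd_sub = 0.15, sd_av = 0.05, sigma = 0.30) {
  sub <- sprintf("S%02d", 1:n_sub)
  av <- sprintf("A%02d", 1:n_av)
  dat <- tibble::tibble(
    subject_id = rep(sub, each = trials_per_sub),
    avatar_id = sample(av, n_sub * trials_per_sub, replace = TRUE),
    direction = sample(c("approach", "avoidance"),
                       n_sub * trials_per_sub, replace = TRUE)
  )
  dat$orientation <- ifelse(match(dat$subject_id, sub) <= 2 * n_sub / 3,
                            "gynophilic", "androphilic")
  dat$avatar_sex <- ifelse(match(dat$avatar_id, av) <= n_av / 2,
                           "male", "female")
  o <- ifelse(dat$orientation == "androphilic", .5, -.5)
  s <- ifelse(dat$avatar_sex == "female", .5, -.5)
  d <- ifelse(dat$direction == "approach", .5, -.5)
  X <- cbind(1, o, s, d, o * s, o * d, s * d, o * s * d)
  u <- rnorm(n_sub, 0, sd_sub)[match(dat$subject_id, sub)]
  v <- rnorm(n_av, 0, sd_av)[match(dat$avatar_id, av)]
  dat$log2_rt <- drop(X %*% beta) + u + v + rnorm(nrow(dat), 0, sigma)
  attr(dat, "beta") <- beta
  dat
}

quiet_fit <- function(...) suppressMessages(fit_model(...))
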