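# Independent oracles, deliberately coded from first principles and kept
# separate from the package implementations they check.

# zero-centred correlation, written cell by cell from the defining formula
# r0 = E[S1 S2] / (sigma1 sigma2), sigma = sqrt(sum(s^2) / n)
oracle_r0 <- function(s1, s2) {
  n <- length(s1)
  e12 <- 0
  for (i in seq_len(n)) e12 <- e12 + s1[i] * s2[i]
  e12 <- e12 / n
  sig1 <- sqrt(sum(s1^2) / n)
  sig2 <- sqrt(sum(s2^2) / n)
  e12 / (sig1 * sig2)
}

# exclusion-circle curve by explicit enumeration at every radius
oracle_curve <- function(points, step = 0.2, stop_frac = 0.02, min_pts = 3) {
  n <- nrow(points)
  d <- sqrt(points[, 1]^2 + points[, 2]^2)
  radii <- numeric(0)
  coefs <- numeric(0)
  x <- 0
  repeat {
    keep <- which(d >= x)
    if (length(keep) < min_pts || length(keep) / n <= stop_frac) break
    r0 <- oracle_r0(points[keep, 1], points[keep, 2])
    r0 <- min(max(r0, -(1 - 1e-10)), 1 - 1e-10)
    radii <- c(radii, x)
    coefs <- c(coefs, atanh(r0))
    x <- x + step
  }
  list(radii = radii, coefs = coefs)
}

# type-7 empirical percentile by sort and index interpolation
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small, fast generator configuration for plumbing tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_channels = 6, n_trials = 12, sampling_rate = 250)
  for (nm in setdiff(names(defaults), names(args))) args[[nm]] <- defaults[[nm]]
  args$rng_seed <- seed
  do.call(generator_config, args)
}

# covariate dataset with one planted coefficient on average_max_effect and
# nine nuisance covariates
synth_dataset <- function(n = 101, beta = 0.6, noise = 0.1, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    session_time_difference = rnorm(n),
    baseline_mean_difference = rnorm(n),
    baseline_sd_difference = rnorm(n),
    average_max_effect = rnorm(n, 2),
    average_min_effect = rnorm(n),
    average_stim_amplitude = rnorm(n),
    stim_amplitude_difference = rnorm(n),
    stim_frequency = rnorm(n),
    stim_depth = rnorm(n),
    task_difference = rbinom(n, 1, 0.5)
  )
  d$max_consistency <- beta * d$average_max_effect + rnorm(n, 0, noise)
  d
}
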