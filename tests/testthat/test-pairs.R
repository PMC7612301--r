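# Stimulation depth, pair covariates, the consistency regression and the
# bootstrap ANOVA.

sphere_points <- function(n, r, seed = 1) {
  set.seed(seed)
  r * stimconsist:::random_directions(n)
}

test_that("depth is +r at the centre of a spherical surface", {
  surf <- sphere_points(400, 50)
  d <- stimulation_depth(c(0, 0, 0), c(0, 0, 0), surf)
  expect_equal(d, 50, tolerance = 0.02)
})

test_that("a midpoint outside the sphere has negative depth", {
  surf <- sphere_points(400, 50)
  d <- stimulation_depth(c(60, 0, 0), c(60, 0, 0), surf)
  expect_equal(d, -10, tolerance = 0.5)
})

test_that("a midpoint on the surface has zero depth", {
  surf <- sphere_points(400, 50)
  p <- surf[7, ]
  expect_equal(stimulation_depth(p, p, surf), 0, tolerance = 1e-9)
})

test_that("the midpoint of the electrode pair is what gets measured", {
  surf <- sphere_points(400, 50)
  # anode and cathode on opposite sides: midpoint at the centre
  d <- stimulation_depth(c(40, 0, 0), c(-40, 0, 0), surf)
  expect_equal(d, 50, tolerance = 0.02)
})

test_that("degenerate surfaces are rejected", {
  expect_error(stimulation_depth(c(0, 0, 0), c(0, 0, 0),
                                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "4 points")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(stimulation_depth(c(0, 0, 0), c(0, 0, 0), flat), "coplanar")
})

make_pair_results <- function(seed = 71, ...) {
  cfg <- generator_config(n_channels = 8, n_trials = 15, rng_seed = seed,
                          effect_map = data.frame(channel = c("E05", "E06"),
                                                  band = "theta", factor = 3),
                          ...)
  pr <- generate_session_pair(cfg, amplitude2 = 2)
  list(res1 = process_session(pr[[1]]), res2 = process_session(pr[[2]]))
}

test_that("pair covariates follow their arithmetic definitions", {
  prs <- make_pair_results()
  cov <- build_pair_covariates(prs$res1, prs$res2)
  expect_equal(cov$session_time_difference, 86400)
  expect_equal(cov$average_stim_amplitude, 1.5)
  expect_equal(cov$stim_amplitude_difference, 1)
  expect_equal(cov$stim_frequency, 50)
  expect_equal(cov$task_difference, 0L)
  u1 <- prs$res1$effect$stimulation$U
  u2 <- prs$res2$effect$stimulation$U
  expect_equal(cov$average_max_effect,
               mean(c(max(u1, na.rm = TRUE), max(u2, na.rm = TRUE))))
  expect_equal(cov$max_consistency,
               consistency_curve(effect_pair_points(
                 prs$res1$effect$stimulation,
                 prs$res2$effect$stimulation))$max_consistency)
})

test_that("a session paired with itself has zero difference covariates", {
  prs <- make_pair_results(seed = 72)
  cov <- build_pair_covariates(prs$res1, prs$res1)
  expect_equal(cov$session_time_difference, 0)
  expect_equal(cov$baseline_mean_difference, 0)
  expect_equal(cov$baseline_sd_difference, 0)
  expect_equal(cov$stim_amplitude_difference, 0)
  expect_equal(cov$task_difference, 0L)
})

test_that("missing metadata is reported by field name", {
  prs <- make_pair_results(seed = 73)
  broken <- prs$res2
  broken$metadata$task_label <- NULL
  expect_error(build_pair_covariates(prs$res1, broken), "task_label")
})

test_that("the planted coefficient is recovered and dominates the ANOVA", {
  d <- synth_dataset(seed = 74)
  fit <- fit_consistency_model(d)
  ci <- confint(fit$lm)["average_max_effect", ]
  expect_gt(0.6, ci[1])
  expect_lt(0.6, ci[2])
  expect_equal(fit$anova$term[which.max(fit$anova$F)], "average_max_effect")
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("a pure-noise response gives small R-squared", {
  d <- synth_dataset(seed = 75)
  d$max_consistency <- rnorm(nrow(d))
  fit <- fit_consistency_model(d)
  expect_lt(fit$r_squared, 0.25)
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("duplicated covariate columns are dropped as aliased", {
  d <- synth_dataset(seed = 76)
  d$stim_depth <- d$average_stim_amplitude
  expect_warning(fit <- fit_consistency_model(d), "aliased")
  expect_false("stim_depth" %in% fit$covariates)
})

test_that("OLS residuals are orthogonal to every covariate column", {
  d <- synth_dataset(seed = 77)
  fit <- fit_consistency_model(d)
  r <- residuals(fit)
  for (v in fit$covariates) {
    expect_lt(abs(sum(r * d[[v]])), 1e-8)
  }
})

test_that("per-term F equals the Type II ANOVA F from car", {
  skip_if_not_installed("car")
  d <- synth_dataset(seed = 78)
  fit <- fit_consistency_model(d)
  a2 <- car::Anova(fit$lm, type = 2)
  expect_equal(fit$anova$F, a2[fit$anova$term, "F value"], tolerance = 1e-8)
})

test_that("bootstrap ANOVA is seeded, sized and degenerately consistent", {
  d <- synth_dataset(n = 40, seed = 79)
  b1 <- bootstrap_anova(d, n_boot = 25, rng_seed = 5)
  b2 <- bootstrap_anova(d, n_boot = 25, rng_seed = 5)
  expect_identical(b1$effects, b2$effects)
  expect_equal(dim(b1$effects), c(25L, 10L))
  # n_boot = 1: the single resample refit matches a direct fit
  b3 <- bootstrap_anova(d, n_boot = 1, rng_seed = 6)
  idx <- stimconsist:::with_seed(6L, sample.int(nrow(d), nrow(d), replace = TRUE))
  refit <- fit_consistency_model(d[idx, ])
  expect_equal(as.numeric(b3$effects[1, refit$anova$term]), refit$anova$F,
               tolerance = 1e-8)
})

test_that("a deterministic response makes its term dominate every resample", {
  d <- synth_dataset(seed = 80)
  d$max_consistency <- 2 * d$baseline_sd_difference
  b <- bootstrap_anova(d, n_boot = 30, rng_seed = 7)
  top <- apply(b$effects, 1, function(f) names(which.max(f)))
  expect_true(all(top == "baseline_sd_difference"))
})

test_that("the bootstrap median concentrates near the full-sample effect", {
  d <- synth_dataset(n = 150, seed = 81)
  fit <- fit_consistency_model(d)
  b <- bootstrap_anova(d, n_boot = 400, rng_seed = 8)
  full <- fit$anova$F[fit$anova$term == "average_max_effect"]
  med <- median(b$effects[, "average_max_effect"])
  expect_lt(abs(med - full) / full, 0.25)
})

test_that("effect-consistency correlation handles exact and degenerate cases", {
  d <- data.frame(average_max_effect = 1:10,
                  max_consistency = 2 * (1:10))
  out <- effect_consistency_correlation(d)
  expect_equal(out$r, 1, tolerance = 1e-12)
  dz <- data.frame(average_max_effect = rep(1, 5), max_consistency = rnorm(5))
  expect_true(effect_consistency_correlation(dz)$degenerate)
  set.seed(82)
  dr <- data.frame(average_max_effect = rnorm(50),
                   max_consistency = rnorm(50))
  out <- effect_consistency_correlation(dr)
  # brute-force covariance / variance oracle
  x <- dr$average_max_effect
  y <- dr$max_consistency
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
})
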