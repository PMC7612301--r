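# Zero-centred correlation, consistency coefficient, exclusion-circle
# curve and the baseline confidence band.

test_that("proportional point sets give r0 = 1 exactly", {
  s1 <- c(1, -2, 3, 0.5)
  expect_equal(zero_centered_correlation(cbind(s1, 4 * s1)), 1)
  expect_equal(zero_centered_correlation(cbind(s1, -4 * s1)), -1)
})

test_that("orthogonal vectors give r0 = 0", {
  expect_equal(zero_centered_correlation(rbind(c(1, 0), c(0, 1))), 0)
})

test_that("r0 matches the brute-force formula on random point sets", {
  set.seed(51)
  err <- replicate(200, {
    n <- sample(3:30, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    abs(zero_centered_correlation(pts) - oracle_r0(pts[, 1], pts[, 2]))
  })
  expect_lt(max(err), 1e-12)
})

test_that("r0 is scale-invariant up to the sign of the scale product", {
  set.seed(52)
  pts <- matrix(rnorm(20), 10, 2)
  r <- zero_centered_correlation(pts)
  for (ab in list(c(2, 3), c(-2, 3), c(-0.5, -4))) {
    scaled <- cbind(ab[1] * pts[, 1], ab[2] * pts[, 2])
    expect_equal(zero_centered_correlation(scaled), sign(prod(ab)) * r,
                 tolerance = 1e-12)
  }
})

test_that("r0 stays in [-1, 1] on random inputs", {
  set.seed(53)
  rs <- replicate(200, {
    n <- sample(3:50, 1)
    zero_centered_correlation(matrix(rnorm(2 * n, sd = 10), n, 2))
  })
  expect_true(all(abs(rs) <= 1 + 1e-12))
})

test_that("the consistency coefficient is atanh(r0) with a finite cap", {
  pts45 <- cbind(1:5, 2 * (1:5))
  expect_equal(consistency_coefficient(pts45), atanh(1 - 1e-10))
  half <- rbind(c(1, 0.5), c(0, sqrt(0.75)))  # r0 = 0.5 by construction
  expect_equal(zero_centered_correlation(half), 0.5, tolerance = 1e-12)
  expect_equal(consistency_coefficient(half), 0.5493, tolerance = 1e-4)
  expect_equal(consistency_coefficient(rbind(c(1, 0), c(0, 1))), 0)
})

test_that("collinear sets reach the cap at every radius", {
  s1 <- seq(0.5, 5, by = 0.5)
  curve <- consistency_curve(cbind(s1, 2 * s1))
  expect_true(all(abs(tanh(curve$coefficient)) > 1 - 1e-9))
  expect_equal(curve$max_consistency, atanh(1 - 1e-10))
  expect_equal(curve$max_radius, 0)  # ties resolved at the smallest radius
})

test_that("hand-enumerated exclusion of a far collinear pair", {
  pts <- rbind(matrix(0.1, 50, 2), c(5, 5), c(6, 6))
  # min_points = 2 admits the two-point tail this construction exercises
  curve <- consistency_curve(pts, min_points = 2)
  i3 <- match(3, curve$radii)
  expect_equal(curve$n_remaining[i3], 2)           # only the two far points
  expect_equal(curve$coefficient[i3], atanh(1 - 1e-10))
  expect_equal(curve$n_remaining[match(0, curve$radii)], 52)
  # radius 0 coefficient computed over all 52 points
  expect_equal(curve$coefficient[1], consistency_coefficient(pts))
  # at the default minimum of 3 points the curve stops before the tail
  expect_true(all(consistency_curve(pts)$n_remaining >= 3))
})

test_that("the curve matches a brute-force enumeration oracle", {
  set.seed(54)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    pts <- matrix(rnorm(2 * n, sd = 2), n, 2)
    curve <- consistency_curve(pts)
    orc <- oracle_curve(pts)
    expect_equal(curve$radii, orc$radii)
    expect_lt(max(abs(tanh(curve$coefficient) - tanh(orc$coefs))), 1e-12)
  }
})

test_that("every reported radius keeps over 2% of points and n is monotone", {
  set.seed(55)
  for (i in 1:20) {
    pts <- matrix(rnorm(100), 50, 2)
    curve <- consistency_curve(pts)
    expect_true(all(curve$n_remaining / curve$n_points > 0.02))
    expect_true(all(diff(curve$n_remaining) <= 0))
  }
})

test_that("swapping the sessions leaves the curve unchanged", {
  set.seed(56)
  pts <- matrix(rnorm(60), 30, 2)
  c1 <- consistency_curve(pts)
  c2 <- consistency_curve(pts[, 2:1])
  expect_equal(c1$coefficient, c2$coefficient, tolerance = 1e-12)
  expect_equal(c1$max_consistency, c2$max_consistency)
})

test_that("fewer than three points is an error", {
  expect_error(consistency_curve(rbind(c(1, 1), c(2, 2))), ">= 3 points")
})

test_that("degenerate identical baseline coefficients give a flat band", {
  pts <- cbind(c(1, 2, 3), c(2, 4, 6))
  pairs <- replicate(25, pts, simplify = FALSE)
  band <- suppressWarnings(baseline_consistency_band(pairs))
  expect_true(all(band$lower == band$upper))
  expect_equal(band$global_upper, max(band$upper))
})

test_that("band percentiles match a sort-and-index oracle", {
  set.seed(57)
  pairs <- replicate(30, matrix(rnorm(80), 40, 2), simplify = FALSE)
  band <- baseline_consistency_band(pairs)
  vals0 <- vapply(pairs, function(p) consistency_coefficient(p), numeric(1))
  expect_equal(band$lower[1], oracle_percentile(vals0, 0.025), tolerance = 1e-12)
  expect_equal(band$upper[1], oracle_percentile(vals0, 0.975), tolerance = 1e-12)
})

test_that("about 5% of held-out null pairs fall outside the band at radius 0", {
  set.seed(58)
  train <- generate_effect_tables(150, 60, rng_seed = 59)
  test <- generate_effect_tables(400, 60, rng_seed = 60)
  band <- baseline_consistency_band(train)
  c0 <- vapply(test, consistency_coefficient, numeric(1))
  outside <- mean(c0 < band$lower[1] | c0 > band$upper[1])
  expect_lt(abs(outside - 0.05), 0.03)
})

test_that("exceedance criteria compare the right curve and band values", {
  pts_strong <- cbind(seq(1, 8, length.out = 40),
                      seq(1, 8, length.out = 40) + rnorm(40, 0, 0.1))
  set.seed(61)
  null_pairs <- generate_effect_tables(50, 40, rng_seed = 62)
  band <- baseline_consistency_band(null_pairs)
  curve <- consistency_curve(pts_strong)
  ex <- exceeds_baseline_band(curve, band)
  expect_true(ex[["radius0"]])
  expect_true(ex[["global"]])
})
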