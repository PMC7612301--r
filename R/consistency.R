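# Cross-session consistency of the stimulation effect.
#
# For a session pair, effect values of corresponding (channel, band) cells
# form points (s1, s2). Consistency is the Fisher-transformed zero-centred
# Pearson correlation: r0 = sum(s1 s2) / sqrt(sum(s1^2) sum(s2^2)), which
# detects proportional agreement through the origin (S1 = k S2, zero
# intercept). The consistency curve recomputes the coefficient while an
# exclusion circle at the origin removes weak-effect cells.

as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("points must be an n x 2 matrix of paired effect values")
  storage.mode(points) <- "double"
  points[stats::complete.cases(points), , drop = FALSE]
}

#' Zero-centred Pearson correlation
#'
#' `r0 = sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))` -- the cosine
#' similarity of the two effect vectors. Unlike the ordinary Pearson
#' correlation it does not centre the variables, so it only detects
#' zero-intercept proportional agreement between the sessions.
#'
#' @param points An n x 2 matrix (or data frame) of paired effect values.
#' @return `r0` in `[-1, 1]`; `NA` (undefined) if either coordinate has zero
#'   sum of squares.
#' @examples
#' s <- cbind(1:5, 2 * (1:5))
#' zero_centered_correlation(s)  # exactly 1
#' @export
zero_centered_correlation <- function(points) {
  points <- as_points(points)
  n1 <- sum(points[, 1L]^2)
  n2 <- sum(points[, 2L]^2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  sum(points[, 1L] * points[, 2L]) / sqrt(n1 * n2)
}

#' Consistency coefficient
#'
#' The Fisher transform (atanh) of the zero-centred correlation. Perfectly
#' collinear point sets give `|r0| = 1`; `r0` is clipped to
#' `+/-(1 - 1e-10)` first, capping the coefficient at about `+/-11.86`.
#'
#' @inheritParams zero_centered_correlation
#' @return The Fisher-transformed coefficient, or `NA` if `r0` is undefined.
#' @export
consistency_coefficient <- function(points) {
  r0 <- zero_centered_correlation(points)
  if (is.na(r0)) return(NA_real_)
  cap <- 1 - 1e-10
  atanh(min(max(r0, -cap), cap))
}

#' Exclusion-circle consistency curve
#'
#' Recomputes the consistency coefficient while an exclusion circle centred
#' at the origin grows in steps of `radius_step`: at radius x only points
#' with `sqrt(s1^2 + s2^2) >= x` are retained (points exactly on the circle
#' are kept). The enlargement stops just before the circle would cover 98%
#' of the points (i.e. every reported radius retains strictly more than
#' `stop_fraction` of the points) or would leave fewer than `min_points`
#' points. The curve's summary is the maximum consistency coefficient: the
#' signed value deviating most from zero, taken at the smallest radius in
#' case of ties (favouring the estimate using more data).
#'
#' @inheritParams zero_centered_correlation
#' @param radius_step Radius increment (default 0.2, in U units).
#' @param stop_fraction Minimum retained fraction of points (default 0.02).
#' @param min_points Minimum points retained at any radius (default 3;
#'   lowering it to 2 admits two-point tail radii, whose coefficients are
#'   degenerate -- any two points are nearly collinear).
#' @return A `consistency_curve`: list with `radii`, `coefficient`,
#'   `n_remaining`, `n_points`, `max_consistency`, `max_radius`.
#' @export
consistency_curve <- function(points, radius_step = 0.2, stop_fraction = 0.02,
                              min_points = 3L) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 3L) stopf("consistency curve needs >= 3 points (have %d)", n)
  dist0 <- sqrt(rowSums(points^2))
  radii <- numeric(0)
  coefs <- numeric(0)
  nrem <- integer(0)
  k <- 0L
  repeat {
    x <- k * radius_step                    # exact grid, no accumulation drift
    keep <- dist0 >= x
    nk <- sum(keep)
    if (nk < min_points || nk / n <= stop_fraction) break
    radii <- c(radii, x)
    nrem <- c(nrem, nk)
    coefs <- c(coefs, consistency_coefficient(points[keep, , drop = FALSE]))
    k <- k + 1L
  }
  if (all(is.na(coefs))) {
    imax <- NA_integer_
    max_c <- NA_real_
    max_r <- NA_real_
  } else {
    imax <- which.max(abs(coefs))  # first index wins ties -> smallest radius
    max_c <- coefs[imax]
    max_r <- radii[imax]
  }
  structure(list(radii = radii, coefficient = coefs, n_remaining = nrem,
                 n_points = n, max_consistency = max_c, max_radius = max_r),
            class = "consistency_curve")
}

#' @export
print.consistency_curve <- function(x, ...) {
  cat(sprintf(
    "Consistency curve: %d points, radii 0..%.1f (step %.1f)\n",
    x$n_points, max(x$radii), if (length(x$radii) > 1L) diff(x$radii)[1L] else 0))
  cat(sprintf("  max consistency %.3f at radius %.1f (n = %d)\n",
              x$max_consistency, x$max_radius,
              x$n_remaining[match(x$max_radius, x$radii)]))
  invisible(x)
}

#' @export
plot.consistency_curve <- function(x, band = NULL, ...) {
  graphics::plot(x$radii, x$coefficient, type = "l",
                 xlab = "exclusion radius (U units)",
                 ylab = "consistency coefficient", ...)
  if (!is.null(band)) {
    common <- intersect(x$radii, band$radii)
    i <- match(common, band$radii)
    graphics::polygon(c(common, rev(common)),
                      c(band$lower[i], rev(band$upper[i])),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  }
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$max_radius, x$max_consistency, pch = 18, col = "brown")
  invisible(x)
}

#' Baseline consistency confidence band
#'
#' Computes the consistency curve for every baseline session pair and, per
#' radius, the two-sided 95% interval (2.5th and 97.5th percentiles) of the
#' baseline coefficients, plus the global maximum of the upper bound across
#' radii (the reference for the "maximum consistency" comparison).
#'
#' @param baseline_pairs List of n x 2 point sets (baseline effect pairs),
#'   or a list of `consistency_curve` objects.
#' @param probs Two-sided percentile levels.
#' @param ... Passed to [consistency_curve()] when point sets are given.
#' @return A `consistency_band`: list with `radii`, `lower`, `upper`,
#'   `n_pairs` (curves contributing per radius), `global_upper`.
#' @export
baseline_consistency_band <- function(baseline_pairs, probs = c(0.025, 0.975),
                                      ...) {
  if (length(baseline_pairs) < 20L) {
    warnf("only %d baseline pairs; percentile band may be unstable",
          length(baseline_pairs))
  }
  curves <- lapply(baseline_pairs, function(p) {
    if (inherits(p, "consistency_curve")) p else consistency_curve(p, ...)
  })
  radii <- sort(unique(unlist(lapply(curves, `[[`, "radii"))))
  lower <- upper <- numeric(length(radii))
  npairs <- integer(length(radii))
  for (i in seq_along(radii)) {
    vals <- unlist(lapply(curves, function(cv) {
      j <- match(radii[i], cv$radii)
      if (is.na(j)) NULL else cv$coefficient[j]
    }))
    vals <- vals[is.finite(vals)]
    npairs[i] <- length(vals)
    q <- stats::quantile(vals, probs, na.rm = TRUE, names = FALSE)
    lower[i] <- q[1]
    upper[i] <- q[2]
  }
  structure(list(radii = radii, lower = lower, upper = upper,
                 n_pairs = npairs, global_upper = max(upper)),
            class = "consistency_band")
}

#' @export
print.consistency_band <- function(x, ...) {
  cat(sprintf("Baseline consistency band over %d radii; global upper bound %.3f\n",
              length(x$radii), x$global_upper))
  invisible(x)
}

#' Does a consistency curve exceed the baseline band?
#'
#' Evaluates the three exceedance criteria used to summarise a study: the
#' curve value at radius 0 against the band's 97.5th percentile at radius 0,
#' the value at radius 3 against the band at radius 3 (NA when either does
#' not reach radius 3), and the maximum consistency against the global
#' maximum of the band's upper bound.
#'
#' @param curve A `consistency_curve` for a stimulation session pair.
#' @param band A `consistency_band` from baseline pairs.
#' @param mid_radius Radius for the intermediate criterion (default 3).
#' @return Logical vector with elements `radius0`, `radius_mid`, `global`.
#' @export
exceeds_baseline_band <- function(curve, band, mid_radius = 3) {
  at <- function(obj, r, field) {
    i <- match(TRUE, abs(obj$radii - r) < 1e-9)
    if (is.na(i)) NA_real_ else obj[[field]][i]
  }
  c(radius0 = unname(at(curve, 0, "coefficient") > at(band, 0, "upper")),
    radius_mid = unname(at(curve, mid_radius, "coefficient") >
                          at(band, mid_radius, "upper")),
    global = unname(curve$max_consistency > band$global_upper))
}

#' Paired effect points for two sessions
#'
#' Builds the (s1, s2) point set from two effect matrices, restricted to
#' the intersection of valid channels and to cells finite in both sessions.
#'
#' @param em1,em2 `effect_matrix` objects.
#' @return An n x 2 matrix with attribute `cells` naming each row's
#'   channel/band.
#' @export
effect_pair_points <- function(em1, em2) {
  ch <- intersect(rownames(em1$U), rownames(em2$U))
  bd <- intersect(colnames(em1$U), colnames(em2$U))
  a <- em1$U[ch, bd, drop = FALSE]
  b <- em2$U[ch, bd, drop = FALSE]
  ok <- is.finite(a) & is.finite(b)
  cells <- outer(ch, bd, paste, sep = ".")
  structure(cbind(s1 = a[ok], s2 = b[ok]), cells = cells[ok])
}
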