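# Session-pair covariates, the multiple linear regression for maximum
# consistency, and the bootstrap ANOVA attribution.

covariate_names <- c(
  "session_time_difference", "baseline_mean_difference",
  "baseline_sd_difference", "average_max_effect", "average_min_effect",
  "average_stim_amplitude", "stim_amplitude_difference", "stim_frequency",
  "stim_depth", "task_difference"
)

#' Build the session-pair covariates
#'
#' Computes the ten covariates used to explain maximum consistency, plus
#' the response, from two processed sessions (see [process_session()]):
#' absolute session start-time difference; mean absolute per-cell
#' difference of baseline log band-power means and of baseline SDs (over
#' both pre and post cells of the common valid channels); the
#' between-session averages of the maximum and minimum stimulation effect
#' (across all common channel/band cells); average stimulation amplitude
#' and absolute amplitude difference; stimulation frequency (must be common
#' within the pair); signed stimulation depth; and a 0/1 task-difference
#' indicator. The response is the pair's maximum consistency coefficient.
#' All differences are absolute, so the covariates are symmetric in session
#' order.
#'
#' @param res1,res2 `stim_session_result` objects from [process_session()].
#' @param surface Brain-surface point set (m x 3, mm); default: the surface
#'   stored with session 1.
#' @param ... Passed to [consistency_curve()].
#' @return One-row data frame with the ten covariates and `max_consistency`,
#'   carrying the stimulation and baseline `consistency_curve`s as
#'   attributes `stim_curve` and `baseline_curve`.
#' @export
build_pair_covariates <- function(res1, res2, surface = NULL, ...) {
  for (f in c("start_timestamp", "amplitude", "frequency", "task_label",
              "anode_xyz", "cathode_xyz")) {
    if (is.null(res1$metadata[[f]]) || is.null(res2$metadata[[f]])) {
      stopf("missing metadata field '%s'", f)
    }
  }
  if (res1$metadata$frequency != res2$metadata$frequency) {
    stopf("stimulation frequency differs within the pair")
  }
  surface <- surface %||% res1$surface
  pts <- effect_pair_points(res1$effect$stimulation, res2$effect$stimulation)
  stim_curve <- consistency_curve(pts, ...)
  base_pts <- effect_pair_points(res1$effect$baseline, res2$effect$baseline)
  base_curve <- consistency_curve(base_pts, ...)
  # baseline log-power statistics restricted to common cells
  b1 <- res1$baseline_stats
  b2 <- res2$baseline_stats
  key <- function(b) paste(b$channel, b$band, b$role, sep = "\r")
  common <- intersect(key(b1), key(b2))
  i1 <- match(common, key(b1))
  i2 <- match(common, key(b2))
  common_ch <- intersect(rownames(res1$effect$stimulation$U),
                         rownames(res2$effect$stimulation$U))
  u1 <- res1$effect$stimulation$U[common_ch, , drop = FALSE]
  u2 <- res2$effect$stimulation$U[common_ch, , drop = FALSE]
  out <- data.frame(
    session_time_difference = abs(res1$metadata$start_timestamp -
                                    res2$metadata$start_timestamp),
    baseline_mean_difference = mean(abs(b1$mean[i1] - b2$mean[i2])),
    baseline_sd_difference = mean(abs(b1$sd[i1] - b2$sd[i2])),
    average_max_effect = mean(c(max(u1, na.rm = TRUE), max(u2, na.rm = TRUE))),
    average_min_effect = mean(c(min(u1, na.rm = TRUE), min(u2, na.rm = TRUE))),
    average_stim_amplitude = mean(c(res1$metadata$amplitude,
                                    res2$metadata$amplitude)),
    stim_amplitude_difference = abs(res1$metadata$amplitude -
                                      res2$metadata$amplitude),
    stim_frequency = res1$metadata$frequency,
    stim_depth = stimulation_depth(res1$metadata$anode_xyz,
                                   res1$metadata$cathode_xyz, surface),
    task_difference = as.integer(res1$metadata$task_label !=
                                   res2$metadata$task_label),
    max_consistency = stim_curve$max_consistency
  )
  attr(out, "stim_curve") <- stim_curve
  attr(out, "baseline_curve") <- base_curve
  out
}

# closed-form OLS with per-term t and F = t^2; returns NULL on rank
# deficiency. X includes the intercept column.
fast_ols <- function(X, y) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  cf <- backsolve(R, forwardsolve(R, crossprod(X, y), upper.tri = TRUE,
                                  transpose = TRUE))
  res <- y - X %*% cf
  dfres <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dfres
  se <- sqrt(diag(chol2inv(R)) * s2)
  tval <- as.numeric(cf) / se
  tss <- sum((y - mean(y))^2)
  list(coef = stats::setNames(as.numeric(cf), colnames(X)), se = se,
       t = tval, F = tval^2, df = dfres, r_squared = 1 - sum(res^2) / tss)
}

#' Fit the consistency regression model
#'
#' Ordinary least squares of the maximum consistency coefficient on the ten
#' session-pair covariates (task difference as a 0/1 indicator). Reports
#' the coefficients, R-squared, adjusted R-squared, and a per-term ANOVA
#' table of F statistics; for this main-effects-only model each term's
#' (Type II) F equals its squared t statistic, which is also what the
#' bootstrap uses. Aliased (rank-deficient) terms are dropped with a
#' warning, as in `lm`.
#'
#' @param dataset Data frame with the covariate columns of
#'   [build_pair_covariates()] and the response `max_consistency`.
#' @param covariates Covariate names to use (default: the canonical ten,
#'   restricted to those present).
#' @return A `consistency_fit`: list with the underlying `lm` fit,
#'   `coefficients`, `r_squared`, `adj_r_squared`, `anova` (term, F, p).
#' @export
fit_consistency_model <- function(dataset, covariates = NULL) {
  covariates <- covariates %||% intersect(covariate_names, names(dataset))
  if (!"max_consistency" %in% names(dataset)) {
    stopf("dataset must contain the response 'max_consistency'")
  }
  if (nrow(dataset) <= length(covariates) + 1L) {
    stopf("need more pairs (%d) than covariates + 1 (%d)",
          nrow(dataset), length(covariates) + 1L)
  }
  fml <- stats::reformulate(covariates, response = "max_consistency")
  fit <- stats::lm(fml, data = dataset)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    warnf("dropping aliased term(s): %s", paste(aliased, collapse = ", "))
    covariates <- setdiff(covariates, aliased)
    fml <- stats::reformulate(covariates, response = "max_consistency")
    fit <- stats::lm(fml, data = dataset)
  }
  sm <- summary(fit)
  tv <- sm$coefficients[-1L, "t value"]
  pv <- sm$coefficients[-1L, "Pr(>|t|)"]
  structure(list(
    lm = fit,
    coefficients = stats::coef(fit),
    covariates = covariates,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    anova = data.frame(term = names(tv), F = unname(tv^2), p = unname(pv),
                       stringsAsFactors = FALSE)
  ), class = "consistency_fit")
}

#' @export
print.consistency_fit <- function(x, ...) {
  cat(sprintf("Consistency model: %d pairs, %d covariates\n",
              stats::nobs(x$lm), length(x$covariates)))
  cat(sprintf("  R-squared %.3f, adjusted R-squared %.3f\n",
              x$r_squared, x$adj_r_squared))
  top <- x$anova[order(-x$anova$F), ][1L, ]
  cat(sprintf("  strongest term: %s (F = %.2f, p = %.3g)\n",
              top$term, top$F, top$p))
  invisible(x)
}

#' @export
summary.consistency_fit <- function(object, ...) {
  print(object)
  cat("\nPer-term ANOVA effects:\n")
  print(object$anova[order(-object$anova$F), ], row.names = FALSE)
  invisible(object)
}

#' @export
coef.consistency_fit <- function(object, ...) object$coefficients

#' @export
predict.consistency_fit <- function(object, newdata = NULL, ...) {
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.consistency_fit <- function(object, ...) stats::residuals(object$lm)

#' Bootstrap the ANOVA effects of the consistency model
#'
#' Resamples session pairs with replacement `n_boot` times, refits the
#' model, and collects the per-term ANOVA F statistics. Rank-deficient
#' bootstrap samples are redrawn. The per-term distributions are summarised
#' with box-plot statistics (median, quartiles, adjacent values under the
#' 1.5 x IQR rule).
#'
#' @inheritParams fit_consistency_model
#' @param n_boot Number of bootstrap samples (default 200).
#' @param rng_seed Integer seed.
#' @return A `bootstrap_anova`: list with `effects` (n_boot x terms matrix
#'   of F statistics), `summary` (box statistics per term), `n_boot`,
#'   `n_redrawn`.
#' @export
bootstrap_anova <- function(dataset, covariates = NULL, n_boot = 200,
                            rng_seed = 1L) {
  covariates <- covariates %||% intersect(covariate_names, names(dataset))
  if (n_boot < 1) stopf("n_boot must be >= 1")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dataset[, covariates, drop = FALSE]))
  y <- dataset$max_consistency
  n <- nrow(X)
  eff <- matrix(NA_real_, n_boot, length(covariates),
                dimnames = list(NULL, covariates))
  n_redrawn <- 0L
  with_seed(rng_seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- fast_ols(X[idx, , drop = FALSE], y[idx])
        if (!is.null(fit)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * n_boot) stopf("bootstrap keeps drawing rank-deficient samples")
      }
      eff[b, ] <- fit$F[-1L]
    }
  })
  summ <- do.call(rbind, lapply(covariates, function(term) {
    x <- eff[, term]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    adj <- adjacent_values(x)
    data.frame(term = term, median = q[2], q1 = q[1], q3 = q[3],
               lower_adjacent = unname(adj["lower"]),
               upper_adjacent = unname(adj["upper"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(effects = eff, summary = summ, n_boot = n_boot,
                 n_redrawn = n_redrawn),
            class = "bootstrap_anova")
}

#' @export
print.bootstrap_anova <- function(x, ...) {
  cat(sprintf("Bootstrap ANOVA effects (%d samples%s)\n", x$n_boot,
              if (x$n_redrawn > 0) sprintf(", %d redrawn", x$n_redrawn) else ""))
  s <- x$summary[order(-x$summary$median), ]
  print(s, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Correlation between average maximum effect and maximum consistency
#'
#' Pearson correlation, across session pairs, of the average maximum
#' effect with the maximum consistency coefficient -- the headline check
#' that stronger band-power increases go with more consistent effects
#' (and its simulated-data null control).
#'
#' @param dataset Data frame with columns `average_max_effect` and
#'   `max_consistency`.
#' @return List with `r`, `p`, `n`.
#' @export
effect_consistency_correlation <- function(dataset) {
  x <- dataset$average_max_effect
  y <- dataset$max_consistency
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stopf("need >= 3 pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), degenerate = TRUE))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
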