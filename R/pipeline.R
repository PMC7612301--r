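# End-to-end orchestration: per-session processing, per-pair consistency,
# study-level summaries (baseline band, exceedance fractions, amplitude /
# frequency screens, regression attribution), and CSV/JSON reporting.

#' Pipeline options
#'
#' Collects the tunable constants of the analysis in one validated list.
#' Defaults are the canonical settings: 1 s segments with 50 ms buffers,
#' 20 s baseline intervals with 5 s guards, 10 s trial grouping, Hamming
#' Welch taper, exclusion-circle step 0.2 stopping before 98% coverage,
#' minimum 10 usable pairs per effect cell, 200 bootstrap samples.
#'
#' @param t1 Artifact criterion-1 threshold (`NULL`: Bonferroni-corrected t
#'   critical value at alpha = 0.05 across channels).
#' @param t2_mult Artifact criterion-2 displacement threshold, in pre-segment
#'   standard deviations.
#' @param welch_window Welch taper (see [welch_psd()]).
#' @param bands Band definitions (see [canonical_bands()]).
#' @param radius_step,stop_fraction,min_points Consistency-curve settings
#'   (see [consistency_curve()]).
#' @param min_pairs Minimum usable pre/post pairs per effect cell.
#' @param continuity Continuity correction in [effect_U()].
#' @param n_boot Bootstrap samples for [bootstrap_anova()].
#' @return A named list of options.
#' @export
pipeline_options <- function(t1 = NULL, t2_mult = 5, welch_window = "hamming",
                             bands = canonical_bands(), radius_step = 0.2,
                             stop_fraction = 0.02, min_points = 3L,
                             min_pairs = 10, continuity = FALSE,
                             n_boot = 200) {
  if (radius_step <= 0) stopf("radius_step must be > 0")
  if (stop_fraction <= 0 || stop_fraction >= 1) stopf("stop_fraction must lie in (0, 1)")
  if (n_boot < 1) stopf("n_boot must be >= 1")
  validate_bands(bands)
  as.list(environment())
}

#' Process one session end to end
#'
#' Runs the full per-session chain: stimulation pre/post segment
#' extraction, artifact-channel detection (on the raw segments), baseline
#' epoch search and pseudo-trial extraction, detrending, common-average
#' re-referencing (stimulation channels excluded from the average but
#' re-referenced; artifact channels dropped), Welch log band power, and the
#' effect matrices U for the stimulation and baseline conditions.
#'
#' @param recording A `session_recording`.
#' @param options A [pipeline_options()] list.
#' @return A `stim_session_result`: list with `effect` (stimulation and
#'   baseline `effect_matrix`), `extrema` (per condition), `baseline_stats`
#'   (per-cell baseline log-power mean/SD), `mask`, `metadata`, counts, and
#'   the session's brain surface.
#' @export
process_session <- function(recording, options = pipeline_options()) {
  validate_session(recording)
  ev <- recording$events
  duration <- ncol(recording$signals) / recording$sampling_rate
  stim_raw <- extract_stim_segments(recording)
  mask <- detect_artifact_channels(stim_raw, t1 = options$t1,
                                   t2_mult = options$t2_mult)
  epochs <- find_baseline_epochs(ev, duration)
  base_raw <- extract_baseline_segments(recording, epochs)
  stim_channels <- unique(c(ev$anode, ev$cathode))
  segs <- detrend_and_center(c(stim_raw, base_raw))
  segs <- common_average_rereference(segs, mask, stim_channels)
  bp <- band_power_table(segs, recording$sampling_rate,
                         bands = options$bands, window = options$welch_window)
  em_stim <- session_effect(bp, "stimulation", session_id = recording$session_id,
                            min_pairs = options$min_pairs,
                            continuity = options$continuity)
  em_base <- session_effect(bp, "baseline", session_id = recording$session_id,
                            min_pairs = options$min_pairs,
                            continuity = options$continuity)
  bl <- bp[bp$condition == "baseline", , drop = FALSE]
  agg_m <- stats::aggregate(log_power ~ channel + band + role, bl, mean)
  agg_s <- stats::aggregate(log_power ~ channel + band + role, bl, stats::sd)
  baseline_stats <- data.frame(agg_m[c("channel", "band", "role")],
                               mean = agg_m$log_power, sd = agg_s$log_power)
  anode <- ev$anode[1L]
  cathode <- ev$cathode[1L]
  structure(list(
    session_id = recording$session_id,
    subject_id = recording$subject_id,
    effect = list(stimulation = em_stim, baseline = em_base),
    extrema = list(stimulation = session_extrema(em_stim),
                   baseline = session_extrema(em_base)),
    baseline_stats = baseline_stats,
    mask = mask,
    metadata = list(
      amplitude = stats::median(ev$amplitude),
      frequency = ev$frequency[1L],
      stim_duration = stats::median(ev$duration),
      start_timestamp = recording$start_timestamp,
      task_label = recording$task_label,
      anode = anode, cathode = cathode,
      anode_xyz = recording$channel_coords[anode, ],
      cathode_xyz = recording$channel_coords[cathode, ]
    ),
    n_stim_pairs = nrow(ev),
    n_baseline_pairs = sum(vapply(base_raw, function(s) s$role == "pre", logical(1))),
    n_excluded_channels = sum(!mask$valid),
    surface = recording$brain_surface
  ), class = "stim_session_result")
}

#' @export
print.stim_session_result <- function(x, ...) {
  cat(sprintf(
    "Processed session %s/%s: %d stim pairs, %d baseline pairs, %d channel(s) excluded\n",
    x$subject_id, x$session_id, x$n_stim_pairs, x$n_baseline_pairs,
    x$n_excluded_channels))
  invisible(x)
}

#' Amplitude and frequency effect screen
#'
#' Session-level Pearson correlations of the per-session effect extrema
#' (minimum and maximum U across all channel/band cells) with the session
#' stimulation amplitude and frequency, plus -- when session pairs are
#' supplied -- the correlation of the absolute between-session effect
#' difference (|t| of [pair_effect_difference()]) with the absolute
#' amplitude difference.
#'
#' @param session_results List of `stim_session_result` (>= 3).
#' @param pair_results Optional list of pair descriptors, each a list with
#'   elements `res1` and `res2` (processed sessions of the pair).
#' @return Data frame with columns `measure`, `covariate`, `r`, `p`, `n`;
#'   `r` is `NA` when a covariate has zero variance.
#' @export
amplitude_effect_screen <- function(session_results, pair_results = NULL) {
  if (length(session_results) < 3L) stopf("need >= 3 sessions")
  ex <- vapply(session_results, function(r) {
    unlist(r$extrema$stimulation[r$extrema$stimulation$band == "all",
                                 c("min", "max")])
  }, numeric(2))
  amp <- vapply(session_results, function(r) r$metadata$amplitude, numeric(1))
  freq <- vapply(session_results, function(r) r$metadata$frequency, numeric(1))
  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  rows <- list(
    c(measure = "min_effect", covariate = "amplitude", safe_cor(ex[1, ], amp)),
    c(measure = "max_effect", covariate = "amplitude", safe_cor(ex[2, ], amp)),
    c(measure = "min_effect", covariate = "frequency", safe_cor(ex[1, ], freq)),
    c(measure = "max_effect", covariate = "frequency", safe_cor(ex[2, ], freq))
  )
  if (!is.null(pair_results) && length(pair_results) >= 3L) {
    dU <- vapply(pair_results, function(p) {
      pair_effect_difference(p$res1$effect$stimulation,
                             p$res2$effect$stimulation)$statistic
    }, numeric(1))
    dA <- vapply(pair_results, function(p) {
      abs(p$res1$metadata$amplitude - p$res2$metadata$amplitude)
    }, numeric(1))
    rows <- c(rows, list(c(measure = "abs_effect_difference",
                           covariate = "abs_amplitude_difference",
                           safe_cor(dU, dA))))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$r <- as.numeric(out$r)
  out$p <- as.numeric(out$p)
  out$n <- as.integer(out$n)
  out
}

#' Run the full study pipeline on synthetic session pairs
#'
#' Generates `n_pairs` session pairs from `config` (with per-pair seeds
#' derived from `seed`), processes every session, computes per-pair
#' stimulation and baseline consistency curves and covariates, the baseline
#' consistency confidence band and the three exceedance criteria (radius 0,
#' radius 3, global maximum), the amplitude/frequency screens, the
#' effect-vs-consistency correlation, and -- when enough pairs are
#' available -- the regression model with bootstrap ANOVA. Optionally
#' writes all result tables plus a run manifest.
#'
#' @param config A [generator_config()] shared by all pairs (per-pair seeds
#'   differ). Alternatively a list of pre-generated session pairs can be
#'   supplied via `session_pairs`.
#' @param n_pairs Number of session pairs to generate.
#' @param options A [pipeline_options()] list.
#' @param seed Integer master seed.
#' @param out_dir Output directory for CSV/JSON reporting, or `NULL`.
#' @param session_pairs Optional list of lists of two `session_recording`s,
#'   bypassing generation.
#' @return A `stim_study` bundle: per-session results, per-pair covariates
#'   and curves, the baseline band, exceedance fractions, screens,
#'   correlation, and (if fitted) `fit` and `bootstrap`.
#' @export
run_pipeline <- function(config = generator_config(), n_pairs = 2,
                         options = pipeline_options(), seed = 1L,
                         out_dir = NULL, session_pairs = NULL) {
  if (is.null(session_pairs)) {
    pair_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_pairs))
    session_pairs <- lapply(seq_len(n_pairs), function(i) {
      cfg <- config
      cfg$rng_seed <- pair_seeds[i]
      generate_session_pair(cfg)
    })
  }
  n_pairs <- length(session_pairs)
  pairs <- vector("list", n_pairs)
  sessions <- list()
  for (i in seq_len(n_pairs)) {
    res1 <- process_session(session_pairs[[i]][[1L]], options)
    res2 <- process_session(session_pairs[[i]][[2L]], options)
    cov <- build_pair_covariates(res1, res2,
                                 radius_step = options$radius_step,
                                 stop_fraction = options$stop_fraction,
                                 min_points = options$min_points)
    pairs[[i]] <- list(pair_id = i, res1 = res1, res2 = res2,
                       covariates = cov,
                       stim_curve = attr(cov, "stim_curve"),
                       baseline_curve = attr(cov, "baseline_curve"))
    sessions <- c(sessions, list(res1, res2))
  }
  covariates <- do.call(rbind, lapply(pairs, `[[`, "covariates"))
  covariates <- cbind(pair_id = seq_len(n_pairs), covariates)
  band <- baseline_consistency_band(lapply(pairs, `[[`, "baseline_curve"))
  exceed <- t(vapply(pairs, function(p) {
    exceeds_baseline_band(p$stim_curve, band)
  }, logical(3)))
  exceed_fraction <- colMeans(exceed, na.rm = TRUE)
  screen <- if (length(sessions) >= 3L) {
    amplitude_effect_screen(sessions, pairs)
  }
  corr <- if (n_pairs >= 3L) effect_consistency_correlation(covariates)
  fit <- boot <- NULL
  if (nrow(covariates) > length(covariate_names) + 1L) {
    fit <- fit_consistency_model(covariates)
    boot <- bootstrap_anova(covariates, covariates = fit$covariates,
                            n_boot = options$n_boot, rng_seed = seed)
  }
  study <- structure(list(
    sessions = sessions, pairs = pairs, covariates = covariates,
    baseline_band = band, exceedance = exceed,
    exceed_fraction = exceed_fraction, screen = screen,
    effect_consistency = corr, fit = fit, bootstrap = boot,
    seed = seed
  ), class = "stim_study")
  if (!is.null(out_dir)) {
    tables <- list(
      effects = do.call(rbind, lapply(sessions, function(s) {
        rbind(effect_matrix_to_df(s$effect$stimulation),
              effect_matrix_to_df(s$effect$baseline))
      })),
      curves = do.call(rbind, lapply(pairs, function(p) {
        curve_to_df(p$stim_curve, p$pair_id)
      })),
      pair_summary = data.frame(
        pair_id = seq_len(n_pairs),
        max_consistency = vapply(pairs, function(p) p$stim_curve$max_consistency,
                                 numeric(1)),
        max_radius = vapply(pairs, function(p) p$stim_curve$max_radius,
                            numeric(1)),
        exceeds_radius0 = exceed[, "radius0"],
        exceeds_radius3 = exceed[, "radius_mid"],
        exceeds_global = exceed[, "global"]
      ),
      covariates = covariates,
      baseline_band = data.frame(radius = band$radii, lower = band$lower,
                                 upper = band$upper, n_pairs = band$n_pairs)
    )
    if (!is.null(boot)) {
      tables$bootstrap <- data.frame(
        term = rep(colnames(boot$effects), each = nrow(boot$effects)),
        bootstrap = rep(seq_len(nrow(boot$effects)), times = ncol(boot$effects)),
        effect = as.numeric(boot$effects)
      )
    }
    if (!is.null(screen)) tables$amplitude_screen <- screen
    write_results(tables, out_dir, seed = seed,
                  config = config[setdiff(names(config), "effect_map")])
  }
  study
}

#' @export
print.stim_study <- function(x, ...) {
  cat(sprintf("Stimulation study: %d sessions, %d pairs\n",
              length(x$sessions), length(x$pairs)))
  cat(sprintf("  exceed baseline band: %.0f%% (radius 0), %.0f%% (radius 3), %.0f%% (global max)\n",
              100 * x$exceed_fraction["radius0"],
              100 * x$exceed_fraction["radius_mid"],
              100 * x$exceed_fraction["global"]))
  if (!is.null(x$effect_consistency)) {
    cat(sprintf("  effect vs consistency: r = %.3f (p = %.3g, n = %d)\n",
                x$effect_consistency$r, x$effect_consistency$p,
                x$effect_consistency$n))
  }
  if (!is.null(x$fit)) {
    cat(sprintf("  model R-squared %.3f (adjusted %.3f)\n",
                x$fit$r_squared, x$fit$adj_r_squared))
  }
  invisible(x)
}
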