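# Seeded synthetic stimulation sessions.
#
# Background activity is per-channel 1/f (pink) noise plus a low-amplitude
# alpha oscillator, so Welch estimates have a realistic spectral slope.
# Stimulation effects are injected by scaling the band-passed component of
# the 1 s post-stimulation window by sqrt(factor) (power scales by the
# factor) under 50 ms cosine ramps, which keeps the modification free of
# edge artifacts. Artifact channels receive an additive 500 uV deflection
# at stimulation offset decaying with tau = 0.8 s, which triggers both
# artifact-rejection criteria by construction.

#' Synthetic session generator configuration
#'
#' Validates and assembles the configuration consumed by
#' [generate_session()] and [generate_session_pair()]. Defaults emulate a
#' typical RAM-style stimulation session: the trial count is drawn as
#' `round(Normal(60, 13.9))` clipped to at least 18, trials come in groups
#' of three with short (4-6 s) inter-stimulus intervals inside a group and
#' long (25-35 s) intervals between groups, at least one of which is forced
#' long enough to host a full baseline epoch.
#'
#' @param n_channels Number of recording channels.
#' @param sampling_rate Sampling rate in Hz (must exceed 110 Hz so the
#'   55 Hz gamma edge is resolvable).
#' @param n_trials Number of stimulation trials, or `NULL` to draw from the
#'   session-size distribution.
#' @param trial_group_size Trials per group (fixed at 3; a leftover smaller
#'   final group is allowed).
#' @param intra_group_gap Range (s) of the inter-stimulus interval within a
#'   group (offset to onset); must stay below the 10 s grouping threshold
#'   once the stimulation duration is added.
#' @param inter_group_gap Range (s) of the interval between groups; the
#'   upper bound must exceed 30 s so baseline epochs exist.
#' @param stim_amplitude Stimulation amplitude in mA, within 0.25-3.5.
#' @param stim_frequency Pulse-train frequency in Hz: 10, 25, 50, 100 or 200.
#' @param stim_duration Stimulation duration in s: 0.5 or 4.6 (4.6 s trains
#'   always use 50 Hz).
#' @param effect_map Data frame with columns `channel`, `band`, `factor`:
#'   multiplicative post-stimulation band-power factors. `NULL` or zero rows
#'   for a null session.
#' @param cross_session_scale Proportionality constant k linking the paired
#'   sessions' effect maps (applied on the log scale).
#' @param effect_noise_sd SD of the session-2 log-factor deviations around
#'   the shared effect map.
#' @param artifact_channels Channel labels receiving the stimulation
#'   artifact.
#' @param rng_seed Integer seed; identical configuration and seed give
#'   bit-identical sessions.
#' @param noise_sd Background pink-noise standard deviation (uV).
#' @param alpha_amplitude Amplitude of the 10 Hz background oscillator (uV).
#' @param lead_in Stimulation-free time before the first trial and after
#'   the last (s).
#' @param max_duration Maximum schedulable session duration (s); an
#'   infeasible timeline is a scheduling error.
#' @param subject_id,task_label,start_timestamp Session metadata.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_channels = 16,
                             sampling_rate = 500,
                             n_trials = NULL,
                             trial_group_size = 3,
                             intra_group_gap = c(4, 6),
                             inter_group_gap = c(25, 35),
                             stim_amplitude = 1,
                             stim_frequency = 50,
                             stim_duration = 0.5,
                             effect_map = NULL,
                             cross_session_scale = 1,
                             effect_noise_sd = 0,
                             artifact_channels = character(0),
                             rng_seed = 1L,
                             noise_sd = 20,
                             alpha_amplitude = 5,
                             lead_in = 10,
                             max_duration = 7200,
                             subject_id = "S001",
                             task_label = "FR1",
                             start_timestamp = 1.6e9) {
  cfg <- as.list(environment())
  if (n_channels < 3) stopf("need at least 3 channels")
  if (sampling_rate <= 2 * 55) stopf("sampling_rate must exceed 110 Hz")
  if (!is.null(n_trials) && n_trials < 1) stopf("n_trials must be positive")
  if (trial_group_size != 3) stopf("trial_group_size is fixed at 3")
  if (any(intra_group_gap <= 0) || any(inter_group_gap <= 0)) {
    stopf("all gaps must be strictly positive")
  }
  if (diff(intra_group_gap) < 0 || diff(inter_group_gap) < 0) {
    stopf("gap ranges must be (min, max)")
  }
  if (inter_group_gap[2] <= 30) {
    stopf("inter_group_gap upper bound must exceed 30 s so baseline epochs exist")
  }
  if (stim_amplitude < 0.25 || stim_amplitude > 3.5) {
    stopf("stim_amplitude must lie in [0.25, 3.5] mA")
  }
  if (!stim_frequency %in% c(10, 25, 50, 100, 200)) {
    stopf("stim_frequency must be one of 10, 25, 50, 100, 200 Hz")
  }
  if (!stim_duration %in% c(0.5, 4.6)) stopf("stim_duration must be 0.5 or 4.6 s")
  if (stim_duration == 4.6 && stim_frequency != 50) {
    stopf("4.6 s stimulation always uses 50 Hz")
  }
  if (intra_group_gap[2] + stim_duration >= 10) {
    stopf("intra_group_gap + stim_duration must stay below the 10 s grouping threshold")
  }
  if (!is.null(effect_map) && nrow(effect_map) > 0) {
    stopifnot(all(c("channel", "band", "factor") %in% names(effect_map)))
    if (any(effect_map$factor <= 0)) stopf("effect factors must be positive")
  }
  class(cfg) <- "generator_config"
  cfg
}

channel_labels_for <- function(n) sprintf("E%02d", seq_len(n))

# uniformly random unit vectors
random_directions <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# spectral envelope for 1/f amplitude shaping on an m-point FFT grid
pink_envelope <- function(m, fs) {
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)                      # two-sided |frequency|
  amp <- numeric(m)
  amp[-1L] <- 1 / sqrt(f[-1L])
  amp
}

# pink (1/f) noise of length n, unit variance, via FFT shaping
pink_noise <- function(n, fs, envelope = NULL) {
  m <- if (is.null(envelope)) stats::nextn(n, c(2, 3, 5)) else length(envelope)
  if (is.null(envelope)) envelope <- pink_envelope(m, fs)
  w <- stats::fft(stats::rnorm(m))
  x <- Re(stats::fft(w * envelope, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# cosine ramp envelope: 1 in the middle, raised-cosine over ramp_n samples
ramp_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0) {
    r <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
    env[seq_len(ramp_n)] <- r
    env[n + 1 - seq_len(ramp_n)] <- r
  }
  env
}

# scale the [low, high) band component of a 1 s window by sqrt(factor)
# under cosine ramps; power in the band scales by ~factor
inject_band_effect <- function(x, fs, low, high, factor, ramp_s = 0.05) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- f >= low & f < high
  band <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  env <- ramp_envelope(n, round(ramp_s * fs))
  x + (sqrt(factor) - 1) * band * env
}

draw_trial_count <- function() {
  max(18L, as.integer(round(stats::rnorm(1, 60, 13.9))))
}

# schedule trial onsets; returns numeric vector of onsets (s)
schedule_trials <- function(cfg, n_trials) {
  gsz <- cfg$trial_group_size
  new_group <- (seq_len(n_trials) - 1L) %% gsz == 0L
  gaps <- ifelse(new_group,
                 stats::runif(n_trials, cfg$inter_group_gap[1], cfg$inter_group_gap[2]),
                 stats::runif(n_trials, cfg$intra_group_gap[1], cfg$intra_group_gap[2]))
  gaps[1L] <- 0
  # force at least one between-group interval long enough for a trimmed
  # epoch hosting a full group of three baseline pseudo-trials
  spacing <- mean(cfg$intra_group_gap) + cfg$stim_duration
  footprint <- 2 + cfg$stim_duration + 0.1
  required <- max(30, 2 * spacing + footprint + 10) + 0.5
  between <- which(new_group & seq_len(n_trials) > 1L)
  if (length(between) > 0 && all(gaps[between] < required)) {
    gaps[between[length(between)]] <- required
  }
  onsets <- cfg$lead_in + cumsum(gaps + c(0, rep(cfg$stim_duration, n_trials - 1L)))
  onsets
}

#' Generate one synthetic stimulation session
#'
#' Produces a complete `session_recording`: pink-noise background with an
#' alpha oscillator on every channel, a stimulation event schedule in
#' groups of three with at least one baseline-capable inter-stimulus
#' interval, band-limited post-stimulation power modulation for every
#' `(channel, band)` entry of the configured effect map, and decaying
#' voltage deflections on the configured artifact channels.
#'
#' @param config A [generator_config()].
#' @param coords,surface Optional electrode coordinates (channels x 3, mm)
#'   and brain-surface point set (m x 3, mm); drawn from the seed when
#'   `NULL`. Used by [generate_session_pair()] to share the geometry.
#' @param effect_map Optional override of `config$effect_map`.
#' @param session_id Session identifier stored in the metadata.
#' @return A `session_recording`: list with `signals` (channels x samples,
#'   uV), `sampling_rate`, `channel_labels`, `channel_coords`, `events`,
#'   `subject_id`, `session_id`, `task_label`, `start_timestamp`,
#'   `brain_surface`.
#' @export
generate_session <- function(config, coords = NULL, surface = NULL,
                             effect_map = NULL, session_id = "ses01") {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(effect_map)) effect_map <- cfg$effect_map
  with_seed(cfg$rng_seed, {
    fs <- cfg$sampling_rate
    labels <- channel_labels_for(cfg$n_channels)
    n_trials <- cfg$n_trials %||% draw_trial_count()
    onsets <- schedule_trials(cfg, n_trials)
    duration <- onsets[n_trials] + cfg$stim_duration + cfg$lead_in
    if (duration > cfg$max_duration) {
      stopf("scheduling error: session duration %.0f s exceeds max_duration %.0f s",
            duration, cfg$max_duration)
    }
    nsamp <- as.integer(round(duration * fs))
    tt <- (seq_len(nsamp) - 1) / fs
    signals <- matrix(0, cfg$n_channels, nsamp, dimnames = list(labels, NULL))
    env <- pink_envelope(stats::nextn(nsamp, c(2, 3, 5)), fs)
    for (ch in seq_len(cfg$n_channels)) {
      osc <- cfg$alpha_amplitude * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
      signals[ch, ] <- cfg$noise_sd * pink_noise(nsamp, fs, env) + osc
    }
    if (is.null(coords)) coords <- 45 * random_directions(cfg$n_channels)
    if (is.null(surface)) surface <- 50 * random_directions(200)
    rownames(coords) <- labels
    events <- data.frame(
      onset = onsets, duration = cfg$stim_duration,
      amplitude = cfg$stim_amplitude, frequency = cfg$stim_frequency,
      anode = labels[1L], cathode = labels[2L], stringsAsFactors = FALSE
    )
    # band-limited effect injection in the post window of every trial
    if (!is.null(effect_map) && nrow(effect_map) > 0) {
      bands <- canonical_bands()
      for (r in seq_len(nrow(effect_map))) {
        ch <- effect_map$channel[r]
        bd <- bands[bands$band == effect_map$band[r], ]
        if (nrow(bd) == 0L) stopf("unknown band '%s' in effect_map", effect_map$band[r])
        if (!ch %in% labels) stopf("unknown channel '%s' in effect_map", ch)
        for (i in seq_len(n_trials)) {
          idx <- segment_indices(onsets[i] + cfg$stim_duration + 0.05, fs)
          signals[ch, idx] <- inject_band_effect(
            signals[ch, idx], fs, bd$low, bd$high, effect_map$factor[r])
        }
      }
    }
    # additive post-stimulation deflection with slow exponential return
    if (length(cfg$artifact_channels) > 0) {
      tau <- 0.8
      dec_n <- as.integer(round(5 * tau * fs))
      dec <- 500 * exp(-(seq_len(dec_n) - 1) / (tau * fs))
      for (ch in cfg$artifact_channels) {
        if (!ch %in% labels) stopf("unknown artifact channel '%s'", ch)
        for (i in seq_len(n_trials)) {
          i0 <- sample_index(onsets[i] + cfg$stim_duration, fs)
          idx <- i0:min(i0 + dec_n - 1L, nsamp)
          signals[ch, idx] <- signals[ch, idx] + dec[seq_along(idx)]
        }
      }
    }
    structure(list(
      signals = signals, sampling_rate = fs, channel_labels = labels,
      channel_coords = coords, events = events,
      subject_id = cfg$subject_id, session_id = session_id,
      task_label = cfg$task_label, start_timestamp = cfg$start_timestamp,
      brain_surface = surface
    ), class = "session_recording")
  })
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "Session %s/%s: %d channels x %.0f s @ %g Hz, %d stimulation trials (%s/%s, %.2g mA, %g Hz, %.1f s)\n",
    x$subject_id, x$session_id, nrow(x$signals),
    ncol(x$signals) / x$sampling_rate, x$sampling_rate, nrow(x$events),
    x$events$anode[1], x$events$cathode[1], x$events$amplitude[1],
    x$events$frequency[1], x$events$duration[1]))
  invisible(x)
}

#' Generate a pair of sessions with a shared stimulation site
#'
#' The two sessions share electrode geometry, brain surface and stimulation
#' location. Session 2's effect map is linked to session 1's through the
#' proportionality constant k (`cross_session_scale`) applied on the log
#' power-ratio scale, plus independent Normal noise of SD `effect_noise_sd`:
#' `log f2 = k * log f1 + noise`. With k = 1 and zero noise the pair shares
#' one effect map exactly; k = -1 reverses every modulation.
#'
#' @param config A [generator_config()]; `rng_seed` seeds the whole pair.
#' @param time_gap Difference between the two start timestamps (s).
#' @param amplitude2,task2 Optional session-2 stimulation amplitude and task
#'   label (default: same as session 1).
#' @return List of two `session_recording`s.
#' @export
generate_session_pair <- function(config, time_gap = 86400,
                                  amplitude2 = NULL, task2 = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$rng_seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
    coords <- 45 * random_directions(cfg$n_channels)
    surface <- 50 * random_directions(200)
    map1 <- cfg$effect_map
    map2 <- map1
    if (!is.null(map1) && nrow(map1) > 0) {
      noise <- stats::rnorm(nrow(map1), 0, cfg$effect_noise_sd)
      map2$factor <- exp(cfg$cross_session_scale * log(map1$factor) + noise)
    }
    cfg1 <- cfg
    cfg1$rng_seed <- sub_seeds[1L]
    ses1 <- generate_session(cfg1, coords = coords, surface = surface,
                             effect_map = map1, session_id = "ses01")
    cfg2 <- cfg
    cfg2$rng_seed <- sub_seeds[2L]
    cfg2$start_timestamp <- cfg$start_timestamp + time_gap
    if (!is.null(amplitude2)) cfg2$stim_amplitude <- amplitude2
    if (!is.null(task2)) cfg2$task_label <- task2
    ses2 <- generate_session(cfg2, coords = coords, surface = surface,
                             effect_map = map2, session_id = "ses02")
    list(ses1, ses2)
  })
}

#' Generate paired effect-value tables directly
#'
#' Bypasses signal processing: for each pair, draws two independent vectors
#' of effect values from a Normal distribution with mean 0 and the given
#' SD, emulating the null in which the two sessions' effect maps are
#' unrelated and match the baseline fluctuation scale. Used for fast
#' statistical control analyses.
#'
#' @param n_pairs Number of session pairs (>= 1).
#' @param n_combinations Number of (channel, band) combinations per session
#'   (>= 3).
#' @param effect_sd Per-session effect SD; 0 yields degenerate all-zero
#'   tables flagged unusable for correlation.
#' @param rng_seed Integer seed.
#' @return List of `n_pairs` matrices (n_combinations x 2, columns `s1`,
#'   `s2`); degenerate tables carry attribute `degenerate = TRUE`.
#' @export
generate_effect_tables <- function(n_pairs, n_combinations, effect_sd = 1,
                                   rng_seed = 1L) {
  if (n_pairs < 1) stopf("n_pairs must be >= 1")
  if (n_combinations < 3) stopf("n_combinations must be >= 3")
  if (effect_sd < 0) stopf("effect_sd must be non-negative")
  with_seed(rng_seed, {
    lapply(seq_len(n_pairs), function(i) {
      m <- cbind(s1 = stats::rnorm(n_combinations, 0, effect_sd),
                 s2 = stats::rnorm(n_combinations, 0, effect_sd))
      if (effect_sd == 0) attr(m, "degenerate") <- TRUE
      m
    })
  })
}
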