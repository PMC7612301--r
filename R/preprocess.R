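# Event-locked preprocessing: baseline epochs, pre/post segment extraction,
# trial grouping, detrending, artifact-channel rejection and common-average
# re-referencing.
#
# Time convention: seconds, 0 = first sample; all intervals half-open
# [start, end). Pre segments end 50 ms before stimulation onset, post
# segments start 50 ms after stimulation offset; both are exactly 1 s long.

new_segment <- function(samples, role, condition, pair_id, group_id, start) {
  list(samples = samples, role = role, condition = condition,
       pair_id = pair_id, group_id = group_id, start = start)
}

#' Find baseline epochs between stimulation events
#'
#' A baseline epoch is any inter-stimulus interval (offset of one event to
#' onset of the next, including the recording edges) at least
#' `min_interval` seconds long, trimmed by `guard` seconds on each side so
#' the epoch stays at least `guard` seconds away from any stimulation.
#'
#' @param events Event table with columns `onset` and `duration` (seconds),
#'   sorted by onset.
#' @param recording_duration Total recording duration in seconds.
#' @param min_interval Minimum stimulation-free interval length (s).
#' @param guard Guard distance from stimulation (s).
#' @return Data frame with columns `start`, `end` (possibly zero rows).
#' @examples
#' ev <- data.frame(onset = c(90, 130), duration = c(10, 0.5))
#' find_baseline_epochs(ev, 140)  # [5, 85) at the edge, then [105, 125)
#' @export
find_baseline_epochs <- function(events, recording_duration,
                                 min_interval = 20, guard = 5) {
  if (nrow(events) > 0 && is.unsorted(events$onset, strictly = FALSE)) {
    stopf("events must be sorted by onset")
  }
  starts <- c(0, events$onset + events$duration)
  ends <- c(events$onset, recording_duration)
  keep <- (ends - starts) >= min_interval
  out <- data.frame(start = starts[keep] + guard, end = ends[keep] - guard)
  out[out$end - out$start > 0, , drop = FALSE]
}

# offset-to-onset gaps between consecutive events
event_gaps <- function(events) {
  if (nrow(events) < 2L) return(numeric(0))
  events$onset[-1L] - (events$onset + events$duration)[-nrow(events)]
}

# group ids (0-based) for events: consecutive events with an inter-stimulus
# gap < group_gap belong to the same group
event_groups <- function(events, group_gap = 10) {
  n <- nrow(events)
  if (n == 0L) return(integer(0))
  cumsum(c(0L, as.integer(event_gaps(events) >= group_gap)))
}

#' Extract pre/post segments around stimulation trials
#'
#' For every stimulation event, extracts a 1 s pre segment ending 50 ms
#' before onset (`[onset - 1.05, onset - 0.05)`) and a 1 s post segment
#' starting 50 ms after offset (`[offset + 0.05, offset + 1.05)`). Events too
#' close to the recording edges are skipped with a warning. Consecutive
#' events with an inter-stimulus interval under 10 s share a group id,
#' reflecting the groups-of-three trial organisation of a typical session.
#'
#' @param recording A `session_recording`.
#' @param buffer Buffer between segment and event (s), default 0.05.
#' @param seg_len Segment length (s), default 1.
#' @param group_gap Grouping threshold on the inter-stimulus interval (s);
#'   gaps strictly below it keep trials in the same group.
#' @return List of segments; each has `samples` (channels x samples matrix),
#'   `role` ("pre"/"post"), `condition` ("stimulation"), `pair_id`,
#'   `group_id`, `start`.
#' @export
extract_stim_segments <- function(recording, buffer = 0.05, seg_len = 1,
                                  group_gap = 10) {
  fs <- recording$sampling_rate
  events <- recording$events
  nsamp <- ncol(recording$signals)
  duration <- nsamp / fs
  groups <- event_groups(events, group_gap)
  segs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    onset <- events$onset[i]
    offset <- onset + events$duration[i]
    pre_start <- onset - buffer - seg_len
    post_start <- offset + buffer
    if (pre_start < 0 || post_start + seg_len > duration) {
      skipped <- skipped + 1L
      next
    }
    pre_idx <- segment_indices(pre_start, fs)
    post_idx <- segment_indices(post_start, fs)
    segs[[length(segs) + 1L]] <- new_segment(
      recording$signals[, pre_idx, drop = FALSE], "pre", "stimulation",
      pair_id = i, group_id = groups[i], start = pre_start)
    segs[[length(segs) + 1L]] <- new_segment(
      recording$signals[, post_idx, drop = FALSE], "post", "stimulation",
      pair_id = i, group_id = groups[i], start = post_start)
  }
  if (skipped > 0L) {
    warnf("%d trial(s) skipped: too close to the recording edges", skipped)
  }
  segs
}

#' Extract baseline pseudo-trial segments from baseline epochs
#'
#' Places pseudo-trials inside each baseline epoch mimicking the timing of
#' the stimulation trials: the pre/post interval equals the session's
#' stimulation duration plus the two 50 ms buffers, pseudo-trials are spaced
#' like the session's median intra-group trial spacing (never closer than
#' one pseudo-trial footprint), grouped in threes, starting at the epoch
#' start. Extraction stops once the number of baseline pairs reaches the
#' number of stimulation pairs, or when the epochs are exhausted.
#'
#' @param recording A `session_recording`.
#' @param epochs Baseline epochs from [find_baseline_epochs()].
#' @param stim_duration Stimulation duration (s); default: median event
#'   duration of the session.
#' @param n_target Maximum number of baseline pairs; default: number of
#'   stimulation events.
#' @param spacing Start-to-start pseudo-trial spacing (s); default: median
#'   intra-group onset-to-onset spacing of the session's events.
#' @param buffer,seg_len As in [extract_stim_segments()].
#' @return List of segments with `condition = "baseline"`.
#' @export
extract_baseline_segments <- function(recording, epochs, stim_duration = NULL,
                                      n_target = NULL, spacing = NULL,
                                      buffer = 0.05, seg_len = 1) {
  fs <- recording$sampling_rate
  events <- recording$events
  if (is.null(stim_duration)) stim_duration <- stats::median(events$duration)
  if (is.null(n_target)) n_target <- nrow(events)
  gap <- stim_duration + 2 * buffer          # pre end -> post start
  footprint <- 2 * seg_len + gap             # one pseudo-trial
  if (is.null(spacing)) {
    g <- event_gaps(events)
    intra <- g[g < 10]
    spacing <- if (length(intra)) stats::median(intra) + stim_duration else footprint
  }
  spacing <- max(spacing, footprint)
  segs <- list()
  pair_id <- 0L
  for (e in seq_len(nrow(epochs))) {
    if (pair_id >= n_target) break
    t0 <- epochs$start[e]
    while (t0 + footprint <= epochs$end[e] && pair_id < n_target) {
      pair_id <- pair_id + 1L
      gid <- (pair_id - 1L) %/% 3L
      pre_start <- t0
      post_start <- t0 + seg_len + gap
      segs[[length(segs) + 1L]] <- new_segment(
        recording$signals[, segment_indices(pre_start, fs), drop = FALSE],
        "pre", "baseline", pair_id = pair_id, group_id = gid, start = pre_start)
      segs[[length(segs) + 1L]] <- new_segment(
        recording$signals[, segment_indices(post_start, fs), drop = FALSE],
        "post", "baseline", pair_id = pair_id, group_id = gid, start = post_start)
      t0 <- t0 + spacing
    }
  }
  segs
}

detrend_matrix <- function(m) {
  n <- ncol(m)
  tc <- seq_len(n) - (n + 1) / 2            # centred time axis
  m <- m - rowMeans(m)
  slope <- as.numeric(m %*% tc) / sum(tc^2)
  m - outer(slope, tc)
}

#' Centre and detrend segments
#'
#' Per channel, subtracts the least-squares line fit over time (removing
#' both mean and linear trend). The operation is a linear projection and
#' therefore idempotent.
#'
#' @param segment A single segment or a list of segments.
#' @return The input with detrended `samples`.
#' @export
detrend_and_center <- function(segment) {
  if (!is.null(segment$samples)) {
    segment$samples <- detrend_matrix(segment$samples)
    return(segment)
  }
  lapply(segment, detrend_and_center)
}

#' Detect channels with repeated stimulation artifacts
#'
#' Flags a channel if either of two criteria holds over the (raw,
#' un-detrended) stimulation segments:
#' \itemize{
#' \item Criterion 1: the absolute paired t statistic, across trials, of the
#'   mean voltage of the first half of the post segment against the mean
#'   voltage of the second half of the pre segment exceeds `t1` (default:
#'   the Bonferroni-corrected two-sided t critical value at alpha = 0.05
#'   across channels).
#' \item Criterion 2: the linear-regression slope of the second half of the
#'   trial-averaged post signal differs from zero at p < 0.05, the fitted
#'   line starts displaced from the pre-segment mean voltage by more than
#'   `t2_mult` pre-segment standard deviations, and the slope trends back
#'   toward the pre-segment mean (a slow return after a deflection).
#' }
#'
#' @param stim_segments Raw stimulation segments from
#'   [extract_stim_segments()] (detection must run before detrending, which
#'   would remove the mean-voltage shifts the criteria measure).
#' @param t1 Criterion-1 threshold; `NULL` for the Bonferroni default.
#' @param t2_mult Criterion-2 displacement threshold in units of the
#'   pre-segment standard deviation.
#' @param slope_alpha Criterion-2 significance level for the slope.
#' @return A `channel_mask`: list with `valid` (named logical), the per
#'   channel criterion statistics, and the thresholds used.
#' @export
detect_artifact_channels <- function(stim_segments, t1 = NULL, t2_mult = 5,
                                     slope_alpha = 0.05) {
  pre <- stim_segments[vapply(stim_segments, function(s) s$role == "pre", logical(1))]
  post <- stim_segments[vapply(stim_segments, function(s) s$role == "post", logical(1))]
  pre <- pre[order(vapply(pre, function(s) s$pair_id, numeric(1)))]
  post <- post[order(vapply(post, function(s) s$pair_id, numeric(1)))]
  labels <- rownames(pre[[1L]]$samples)
  nch <- length(labels)
  n <- length(pre)
  mask <- list(valid = stats::setNames(rep(TRUE, nch), labels))
  if (n < 10L) {
    warnf("only %d stimulation pairs; artifact detection skipped (all channels kept)", n)
    class(mask) <- "channel_mask"
    return(mask)
  }
  nsamp <- ncol(pre[[1L]]$samples)
  h1 <- seq_len(nsamp %/% 2L)              # first half
  h2 <- (nsamp %/% 2L + 1L):nsamp          # second half
  # criterion 1: trials x channels matrices of window-mean voltages
  win_means <- function(lst, cols) {
    m <- vapply(lst, function(s) rowMeans(s$samples[, cols, drop = FALSE]), numeric(nch))
    if (is.null(dim(m))) m <- matrix(m, nrow = nch)
    t(m)
  }
  post_first <- win_means(post, h1)
  pre_second <- win_means(pre, h2)
  d <- post_first - pre_second
  tstat <- colMeans(d) / (apply(d, 2L, stats::sd) / sqrt(n))
  if (is.null(t1)) t1 <- stats::qt(1 - 0.025 / nch, df = n - 1L)
  crit1 <- abs(tstat) > t1
  # criterion 2: slow return of the trial-averaged post signal
  avg_post <- Reduce(`+`, lapply(post, `[[`, "samples")) / n
  pre_all <- do.call(cbind, lapply(pre, `[[`, "samples"))
  pre_mean <- rowMeans(pre_all)
  pre_sd <- apply(pre_all, 1L, stats::sd)
  tc <- h2 - h2[1L]
  tc_c <- tc - mean(tc)
  seg2 <- avg_post[, h2, drop = FALSE]
  slope <- as.numeric(seg2 %*% tc_c) / sum(tc_c^2)
  fitted0 <- rowMeans(seg2) - slope * mean(tc)   # fitted value at start of half
  resid <- seg2 - rowMeans(seg2) - outer(slope, tc_c)
  se <- sqrt(rowSums(resid^2) / (length(tc) - 2L) / sum(tc_c^2))
  slope_p <- 2 * stats::pt(abs(slope / se), df = length(tc) - 2L, lower.tail = FALSE)
  displacement <- fitted0 - pre_mean
  crit2 <- slope_p < slope_alpha &
    abs(displacement) > t2_mult * pre_sd &
    sign(slope) == -sign(displacement)
  crit2[is.na(crit2)] <- FALSE
  crit1[is.na(crit1)] <- FALSE
  mask$valid[] <- !(crit1 | crit2)
  mask$t_stat <- stats::setNames(tstat, labels)
  mask$slope_p <- stats::setNames(slope_p, labels)
  mask$displacement <- stats::setNames(displacement, labels)
  mask$t1 <- t1
  mask$t2 <- t2_mult * pre_sd
  class(mask) <- "channel_mask"
  mask
}

#' Common-average re-reference segments
#'
#' At every time point the mean over valid, non-stimulating channels is
#' subtracted from every retained channel. Stimulation channels are excluded
#' from the common-average calculation but the average is applied to them;
#' artifact channels are dropped from the output entirely.
#'
#' @param segments List of segments.
#' @param mask A `channel_mask` from [detect_artifact_channels()] (or `NULL`
#'   to keep all channels).
#' @param stim_channels Labels of the anode/cathode channels.
#' @return The segments, re-referenced and restricted to valid channels.
#' @export
common_average_rereference <- function(segments, mask = NULL,
                                       stim_channels = character(0)) {
  if (length(segments) == 0L) return(segments)
  labels <- rownames(segments[[1L]]$samples)
  valid <- if (is.null(mask)) stats::setNames(rep(TRUE, length(labels)), labels) else mask$valid[labels]
  contributors <- labels[valid & !(labels %in% stim_channels)]
  if (length(contributors) < 2L) {
    stopf("common average needs >= 2 valid non-stimulation channels (have %d)",
          length(contributors))
  }
  retained <- labels[valid]
  lapply(segments, function(seg) {
    avg <- colMeans(seg$samples[contributors, , drop = FALSE])
    seg$samples <- sweep(seg$samples[retained, , drop = FALSE], 2L, avg)
    seg
  })
}
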