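# Welch power spectral density and log band power.
#
# One-second segments are analysed with Welch's method using a window of
# half the segment length and an overlap of a quarter of the segment length,
# i.e. exactly three tapered windows per segment. At 500 Hz this gives a
# 2 Hz frequency grid, enough to cover every canonical band with >= 2 points.

welch_window <- function(n, type = c("hamming", "hann", "rect")) {
  type <- match.arg(type)
  switch(type,
    hamming = as.numeric(signal::hamming(n)),
    hann    = as.numeric(signal::hanning(n)),
    rect    = rep(1, n)
  )
}

# Welch PSD for a channels x samples matrix; returns list(freq, psd) with
# psd a nfreq x nchannels matrix. Shared workhorse for welch_psd() and
# band_power_table().
welch_psd_multi <- function(x, sampling_rate, window = "hamming") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  fs <- sampling_rate
  if (n != as.integer(round(fs))) {
    stopf("segment length (%d) must equal one second of samples (%d)", n, round(fs))
  }
  wlen <- n %/% 2L
  step <- n %/% 4L
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  w <- welch_window(wlen, window)
  nch <- nrow(x)
  nwin <- length(starts)
  # stack all (window, channel) slices column-wise and FFT once
  m <- matrix(0, wlen, nch * nwin)
  for (k in seq_len(nwin)) {
    idx <- starts[k]:(starts[k] + wlen - 1L)
    m[, ((k - 1L) * nch + 1L):(k * nch)] <- t(x[, idx, drop = FALSE])
  }
  m <- m * w
  sp <- Mod(stats::mvfft(m))^2 / (fs * sum(w^2))
  nfreq <- wlen %/% 2L + 1L
  psd <- matrix(0, nfreq, nch)
  for (k in seq_len(nwin)) {
    psd <- psd + sp[seq_len(nfreq), ((k - 1L) * nch + 1L):(k * nch), drop = FALSE]
  }
  psd <- psd / nwin
  # one-sided scaling: double everything except DC and (for even wlen) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (wlen %% 2L == 0L) dbl[nfreq] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(nfreq) - 1L) * fs / wlen, psd = psd)
}

#' Welch power spectral density of a one-second segment channel
#'
#' Estimates the one-sided PSD of a single 1 s series with Welch's method:
#' window length equal to half the segment length, overlap equal to a
#' quarter of the segment length (three windows per segment). The default
#' taper is Hamming; the taper shifts absolute levels but cancels in the
#' paired pre/post statistics downstream.
#'
#' @param x Numeric vector, exactly one second of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Taper: `"hamming"` (default), `"hann"` or `"rect"`.
#' @return A list with `freq` (Hz) and `psd` (uV^2/Hz), one value per
#'   frequency bin up to Nyquist.
#' @examples
#' x <- sin(2 * pi * 6 * seq(0, 1, length.out = 501)[-501])
#' p <- welch_psd(x, 500)
#' p$freq[which.max(p$psd)]  # 6 Hz
#' @export
welch_psd <- function(x, sampling_rate, window = "hamming") {
  out <- welch_psd_multi(matrix(x, nrow = 1L), sampling_rate, window)
  list(freq = out$freq, psd = as.numeric(out$psd))
}

# Weights integrating the piecewise-linear PSD interpolant exactly over
# [low, high] (band edges off the grid are interpolated, so contiguous
# bands integrate additively); returns a weight vector over the full grid.
band_weights <- function(freq, low, high) {
  if (sum(freq >= low & freq <= high) < 2L) {
    stopf("frequency grid too coarse to cover band [%g, %g) with >= 2 points", low, high)
  }
  if (low < freq[1L] || high > freq[length(freq)]) {
    stopf("frequency grid does not span band [%g, %g)", low, high)
  }
  w <- numeric(length(freq))
  for (k in seq_len(length(freq) - 1L)) {
    a <- max(freq[k], low)
    b <- min(freq[k + 1L], high)
    if (b <= a) next
    h <- freq[k + 1L] - freq[k]
    ta <- (a - freq[k]) / h
    tb <- (b - freq[k]) / h
    w[k] <- w[k] + (b - a) * (1 - (ta + tb) / 2)
    w[k + 1L] <- w[k + 1L] + (b - a) * (ta + tb) / 2
  }
  w
}

#' Log band power from a PSD
#'
#' Integrates the PSD over each band with the trapezoidal rule and returns
#' the natural log of the integral. Powers are floored at `floor` before the
#' log so that degenerate all-zero segments stay finite.
#'
#' @param freq Frequency grid in Hz (must cover 2-55 Hz for the default bands).
#' @param psd PSD values on `freq` (vector), in uV^2/Hz.
#' @param bands Band definition data frame as [canonical_bands()].
#' @param floor Lower bound applied to each band integral before the log.
#' @return Named numeric vector of log band powers, one per band.
#' @examples
#' p <- welch_psd(rnorm(500), 500)
#' band_power(p$freq, p$psd)
#' @export
band_power <- function(freq, psd, bands = canonical_bands(), floor = 1e-12) {
  bands <- validate_bands(bands)
  out <- vapply(seq_len(nrow(bands)), function(i) {
    w <- band_weights(freq, bands$low[i], bands$high[i])
    log(max(sum(w * psd), floor))
  }, numeric(1))
  names(out) <- bands$band
  out
}

#' Log band power table for a set of segments
#'
#' Runs Welch PSD estimation and band-power integration over every segment
#' and channel, producing the long-format table consumed by
#' [session_effect()].
#'
#' @param segments List of segments as produced by [extract_stim_segments()]
#'   / [extract_baseline_segments()] (after detrending and re-referencing).
#' @param sampling_rate Sampling rate in Hz.
#' @param bands Band definitions.
#' @param window Welch taper, see [welch_psd()].
#' @return Data frame with columns `pair_id`, `role` ("pre"/"post"),
#'   `condition` ("stimulation"/"baseline"), `group_id`, `channel`, `band`,
#'   `log_power`.
#' @export
band_power_table <- function(segments, sampling_rate, bands = canonical_bands(),
                             window = "hamming") {
  bands <- validate_bands(bands)
  if (length(segments) == 0L) {
    return(data.frame(pair_id = integer(), role = character(),
                      condition = character(), group_id = integer(),
                      channel = character(), band = character(),
                      log_power = numeric(), stringsAsFactors = FALSE))
  }
  # integration weight matrix: nbands x nfreq, built from the first segment
  probe <- welch_psd_multi(segments[[1L]]$samples, sampling_rate, window)
  wmat <- t(vapply(seq_len(nrow(bands)), function(i) {
    band_weights(probe$freq, bands$low[i], bands$high[i])
  }, numeric(length(probe$freq))))
  floor_p <- 1e-12
  rows <- lapply(segments, function(seg) {
    psd <- welch_psd_multi(seg$samples, sampling_rate, window)$psd
    bp <- log(pmax(wmat %*% psd, floor_p))  # nbands x nch
    labels <- rownames(seg$samples)
    data.frame(
      pair_id = seg$pair_id, role = seg$role, condition = seg$condition,
      group_id = seg$group_id,
      channel = rep(labels, each = nrow(bands)),
      band = rep(bands$band, times = length(labels)),
      log_power = as.numeric(bp), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
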