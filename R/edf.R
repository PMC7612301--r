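# Minimal EDF (European Data Format) reader/writer, base R only.
#
# Scope: continuous multichannel signals, one data record per second, a
# common sampling rate across channels, 16-bit samples. The physical range
# is set per channel to the observed min/max so the full 16-bit resolution
# is used; the round trip is lossy only at the quantisation level
# (range / 65535 per sample). Signals are zero-padded to a whole number of
# records; the exact sample count travels in the session metadata.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

# format a number into at most 8 ASCII characters without corrupting it
edf_num <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 8L) return(s)
    }
    stopf("cannot format %g into an 8-character EDF field", v)
  }, character(1))
}

#' Write signals to an EDF file
#'
#' @param path Output path.
#' @param signals Channels x samples numeric matrix (uV) with channel
#'   labels as row names.
#' @param sampling_rate Sampling rate in Hz (integral).
#' @param patient_id,recording_id Free-text EDF header fields.
#' @param start Start time as seconds since the epoch (stamped into the EDF
#'   start date/time fields, UTC).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, sampling_rate,
                      patient_id = "X", recording_id = "X", start = 0) {
  ns <- nrow(signals)
  fs <- as.integer(round(sampling_rate))
  nsamp <- ncol(signals)
  n_rec <- as.integer(ceiling(nsamp / fs))
  labels <- rownames(signals) %||% channel_labels_for(ns)
  pmin_ <- apply(signals, 1L, min)
  pmax_ <- apply(signals, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  margin <- 1e-3 * (pmax_ - pmin_)          # keeps samples in range after the
  pmin_ <- pmin_ - margin                   # 8-character header rounding
  pmax_ <- pmax_ + margin
  dmin <- -32768L
  dmax <- 32767L
  st <- as.POSIXct(start, origin = "1970-01-01", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8L)
  wr(patient_id, 80L)
  wr(recording_id, 80L)
  wr(format(st, "%d.%m.%y"), 8L)
  wr(format(st, "%H.%M.%S"), 8L)
  wr(256L * (ns + 1L), 8L)
  wr("", 44L)
  wr(n_rec, 8L)
  wr("1", 8L)                               # record duration: 1 s
  wr(ns, 4L)
  wr(labels, 16L)
  wr(rep("", ns), 80L)                      # transducer
  wr(rep("uV", ns), 8L)
  pmin_ <- as.numeric(edf_num(pmin_))       # store exactly what the header says
  pmax_ <- as.numeric(edf_num(pmax_))
  wr(edf_num(pmin_), 8L)
  wr(edf_num(pmax_), 8L)
  wr(rep(dmin, ns), 8L)
  wr(rep(dmax, ns), 8L)
  wr(rep("", ns), 80L)                      # prefiltering
  wr(rep(fs, ns), 8L)
  wr(rep("", ns), 32L)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  pad <- n_rec * fs - nsamp
  if (pad > 0) signals <- cbind(signals, matrix(0, ns, pad))
  dig <- round((signals - pmin_) / scale) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  # records: per second, channels sequentially
  arr <- array(t(dig), dim = c(fs, n_rec, ns))
  out <- as.integer(aperm(arr, c(1L, 3L, 2L)))
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (channels x samples matrix, physical units,
#'   labels as row names), `sampling_rate`, `n_records`, `start_date`,
#'   `start_time`.
#' @export
read_edf <- function(path) {
  con <- tryCatch(file(path, "rb"), error = function(e) {
    stopf("format error: cannot open EDF file '%s'", path)
  })
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8L)
  if (version != "0") stopf("format error: '%s' is not an EDF file", path)
  rd(80L); rd(80L)
  start_date <- rd(8L)
  start_time <- rd(8L)
  rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stopf("format error: bad signal count in '%s'", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- rdv(16L)
  rdv(80L); rdv(8L)
  pmin_ <- as.numeric(rdv(8L))
  pmax_ <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L))
  dmax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  if (length(unique(spr)) != 1L) stopf("format error: mixed sampling rates unsupported")
  fs <- spr[1L] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr)) stopf("format error: truncated EDF data in '%s'", path)
  arr <- array(raw, dim = c(spr[1L], ns, n_rec))
  dig <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  signals <- dig * scale + (pmin_ - dmin * scale)
  rownames(signals) <- labels
  list(signals = signals, sampling_rate = fs, n_records = n_rec,
       start_date = start_date, start_time = start_time)
}
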