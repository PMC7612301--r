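# Session persistence: EDF for signals, TSV for the event table, JSON for
# metadata (including electrode coordinates and the brain-surface point
# set), CSV for derived tables plus a JSON run manifest.

#' Write a session to disk
#'
#' Writes three files under `dir`: `<stem>.edf` (signals),
#' `<stem>_events.tsv` (columns `onset_s`, `duration_s`, `amplitude_mA`,
#' `frequency_Hz`, `anode`, `cathode`) and `<stem>_meta.json` (subject,
#' session, task, start timestamp, exact sample count, electrode
#' coordinates, brain surface).
#'
#' @param recording A `session_recording`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; default `subject_session`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_session <- function(recording, dir, stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% paste(recording$subject_id, recording$session_id, sep = "_")
  paths <- c(
    signal = file.path(dir, paste0(stem, ".edf")),
    events = file.path(dir, paste0(stem, "_events.tsv")),
    meta = file.path(dir, paste0(stem, "_meta.json"))
  )
  write_edf(paths["signal"], recording$signals, recording$sampling_rate,
            patient_id = recording$subject_id,
            recording_id = recording$session_id,
            start = recording$start_timestamp)
  ev <- recording$events
  utils::write.table(
    data.frame(onset_s = ev$onset, duration_s = ev$duration,
               amplitude_mA = ev$amplitude, frequency_Hz = ev$frequency,
               anode = ev$anode, cathode = ev$cathode),
    paths["events"], sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    subject_id = recording$subject_id,
    session_id = recording$session_id,
    task_label = recording$task_label,
    start_timestamp = recording$start_timestamp,
    sampling_rate = recording$sampling_rate,
    n_samples = ncol(recording$signals),
    channel_labels = recording$channel_labels,
    channel_coords = unname(apply(recording$channel_coords, 1L, as.numeric,
                                  simplify = FALSE)),
    brain_surface = unname(apply(recording$brain_surface, 1L, as.numeric,
                                 simplify = FALSE))
  )
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a session from disk
#'
#' Reads and validates the three-file session layout written by
#' [write_session()]. The sampling rate comes from the EDF header; channel
#' labels referenced by events are resolved against the EDF labels; events
#' must lie inside the recorded duration.
#'
#' @param signal_path EDF file.
#' @param events_path Tab-separated event table.
#' @param meta_path JSON metadata file.
#' @return A validated `session_recording`.
#' @export
read_session <- function(signal_path, events_path, meta_path) {
  edf <- read_edf(signal_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "amplitude_mA", "frequency_Hz",
            "anode", "cathode")
  if (!all(need %in% names(ev))) {
    stopf("format error: event table must have columns %s",
          paste(need, collapse = ", "))
  }
  signals <- edf$signals
  if (!is.null(meta$n_samples) && meta$n_samples <= ncol(signals)) {
    signals <- signals[, seq_len(meta$n_samples), drop = FALSE]
  }
  events <- data.frame(onset = ev$onset_s, duration = ev$duration_s,
                       amplitude = ev$amplitude_mA, frequency = ev$frequency_Hz,
                       anode = ev$anode, cathode = ev$cathode,
                       stringsAsFactors = FALSE)
  labels <- rownames(signals)
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  rec <- structure(list(
    signals = signals, sampling_rate = edf$sampling_rate,
    channel_labels = labels,
    channel_coords = as_mat(meta$channel_coords),
    events = events,
    subject_id = meta$subject_id, session_id = meta$session_id,
    task_label = meta$task_label, start_timestamp = meta$start_timestamp,
    brain_surface = as_mat(meta$brain_surface)
  ), class = "session_recording")
  if (!is.null(rec$channel_coords)) rownames(rec$channel_coords) <- labels
  validate_session(rec)
}

#' Validate a session recording
#'
#' Checks the `session_recording` invariants: events sorted and
#' non-overlapping, anode/cathode labels present among the channel labels,
#' finite signals, events inside the recording, and a sampling rate
#' resolving the 55 Hz gamma edge.
#'
#' @param recording A `session_recording`.
#' @return The recording, invisibly, or an error.
#' @export
validate_session <- function(recording) {
  ev <- recording$events
  labels <- recording$channel_labels
  if (is.unsorted(ev$onset)) stopf("events must be sorted by onset")
  if (nrow(ev) > 1L) {
    if (any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)])) {
      stopf("consecutive events overlap")
    }
  }
  bad <- setdiff(unique(c(ev$anode, ev$cathode)), labels)
  if (length(bad) > 0) {
    stopf("reference error: event channel(s) %s absent from the recording",
          paste(bad, collapse = ", "))
  }
  duration <- ncol(recording$signals) / recording$sampling_rate
  if (nrow(ev) > 0 && any(ev$onset + ev$duration > duration)) {
    stopf("bounds error: event extends beyond the recorded signal")
  }
  if (any(!is.finite(recording$signals))) stopf("signals must be finite")
  if (recording$sampling_rate <= 110) {
    stopf("sampling rate must exceed 110 Hz to resolve the gamma band")
  }
  invisible(recording)
}

# flatten an effect matrix to the long CSV schema
effect_matrix_to_df <- function(em) {
  U <- em$U
  data.frame(
    session = em$session_id %||% NA_character_,
    condition = em$condition,
    channel = rep(rownames(U), times = ncol(U)),
    band = rep(colnames(U), each = nrow(U)),
    U = as.numeric(U),
    n_pairs = as.integer(em$n_pairs),
    stringsAsFactors = FALSE
  )
}

curve_to_df <- function(curve, pair_id = NA) {
  data.frame(pair_id = pair_id, radius = curve$radii,
             n_remaining = curve$n_remaining,
             coefficient = curve$coefficient)
}

#' Write derived result tables and a run manifest
#'
#' Writes every supplied table as CSV under `out_dir` plus `manifest.json`
#' recording the seed, a configuration fingerprint and the package version,
#' so a run can be reproduced exactly.
#'
#' @param tables Named list; each element is a data frame (written as
#'   `<name>.csv`), an `effect_matrix`, or a `consistency_curve`.
#' @param out_dir Output directory (created if missing).
#' @param seed,config Seed and configuration to record in the manifest
#'   (`config` is serialised to JSON and fingerprinted).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- tryCatch({dir.create(out_dir, recursive = TRUE); TRUE},
                   warning = function(w) FALSE)
    if (!ok || !dir.exists(out_dir)) stopf("I/O error: cannot create '%s'", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (inherits(tb, "effect_matrix")) tb <- effect_matrix_to_df(tb)
    if (inherits(tb, "consistency_curve")) tb <- curve_to_df(tb)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg_json <- if (is.null(config)) "" else {
    as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                  force = TRUE))
  }
  manifest <- list(
    seed = seed,
    config_hash = config_hash(cfg_json),
    package_version = as.character(utils::packageVersion("stimconsist")),
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, mp))
}
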