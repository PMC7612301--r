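# Segment arithmetic, baseline epochs, grouping, detrending, artifact
# detection, common-average re-referencing.

make_recording <- function(events, duration = 200, n_channels = 4, fs = 200,
                           signal_fn = NULL) {
  nsamp <- as.integer(duration * fs)
  labels <- sprintf("E%02d", seq_len(n_channels))
  signals <- if (is.null(signal_fn)) {
    matrix(rnorm(n_channels * nsamp), n_channels, nsamp)
  } else {
    signal_fn(n_channels, nsamp)
  }
  rownames(signals) <- labels
  structure(list(
    signals = signals, sampling_rate = fs, channel_labels = labels,
    channel_coords = matrix(rnorm(n_channels * 3), n_channels, 3,
                            dimnames = list(labels, NULL)),
    events = events, subject_id = "T01", session_id = "s1",
    task_label = "FR1", start_timestamp = 0,
    brain_surface = 50 * stimconsist:::random_directions(50)
  ), class = "session_recording")
}

stim_events <- function(onsets, duration = 0.5) {
  n <- length(onsets)
  data.frame(onset = onsets, duration = rep(duration, n),
             amplitude = rep(1, n), frequency = rep(50, n),
             anode = rep("E01", n), cathode = rep("E02", n),
             stringsAsFactors = FALSE)
}

test_that("a 30 s inter-stimulus interval yields the epoch trimmed by 5 s", {
  ev <- data.frame(onset = c(95, 130), duration = c(5, 1))
  ep <- find_baseline_epochs(ev, 200)
  i <- which(ep$start == 105)
  expect_length(i, 1)
  expect_equal(ep$end[i], 125)
})

test_that("intervals under 20 s yield no epoch", {
  ev <- data.frame(onset = c(50, 100 + 19.9), duration = c(50, 1))
  ep <- find_baseline_epochs(ev, 125)
  expect_false(any(ep$start > 100 & ep$end < 120))
})

test_that("a stimulation-free recording yields one edge-guarded epoch", {
  ev <- data.frame(onset = numeric(0), duration = numeric(0))
  ep <- find_baseline_epochs(ev, 120)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 5)
  expect_equal(ep$end, 115)
})

test_that("pre/post windows sit 50 ms from onset and offset", {
  set.seed(21)
  rec <- make_recording(stim_events(50), duration = 100)
  segs <- extract_stim_segments(rec)
  pre <- segs[[1]]
  post <- segs[[2]]
  expect_equal(pre$start, 48.95)
  expect_equal(post$start, 50.55)
  expect_equal(ncol(pre$samples), 200)  # exactly 1 s at 200 Hz
  # samples must match the raw signal at those indices
  idx <- stimconsist:::segment_indices(48.95, 200)
  expect_identical(pre$samples, rec$signals[, idx])
})

test_that("every event away from the edges yields one pre/post pair", {
  set.seed(22)
  onsets <- seq(20, 260, by = 4)  # 61 events
  rec <- make_recording(stim_events(onsets), duration = 300)
  segs <- extract_stim_segments(rec)
  expect_equal(length(segs), 2 * length(onsets))
  roles <- vapply(segs, `[[`, "", "role")
  expect_equal(sum(roles == "pre"), length(onsets))
})

test_that("events too close to the recording edge are skipped with a warning", {
  set.seed(23)
  rec <- make_recording(stim_events(c(0.5, 50)), duration = 100)
  expect_warning(segs <- extract_stim_segments(rec), "skipped")
  expect_equal(length(segs), 2)
})

test_that("trials under 10 s apart share a group id", {
  set.seed(24)
  onsets <- c(20, 24.5, 29, 69)  # gaps 4, 4, 39.5 (offset to onset)
  rec <- make_recording(stim_events(onsets), duration = 100)
  segs <- extract_stim_segments(rec)
  gids <- vapply(segs[seq(1, 8, by = 2)], `[[`, 0L, "group_id")
  expect_equal(gids, c(0L, 0L, 0L, 1L))
})

test_that("baseline pseudo-trials mirror the stimulation pre/post interval", {
  set.seed(25)
  rec <- make_recording(stim_events(numeric(0)), duration = 60)
  ep <- data.frame(start = 5, end = 55)
  segs <- extract_baseline_segments(rec, ep, stim_duration = 0.5, n_target = 6,
                                    spacing = 5)
  pre <- segs[[1]]
  post <- segs[[2]]
  expect_equal(post$start - (pre$start + 1), 0.6)  # gap = duration + 2 buffers
  gids <- vapply(segs, `[[`, 0L, "group_id")
  expect_equal(unique(gids[1:6]), 0L)  # first three pairs share a group
})

test_that("a 12 s epoch fits only one 4.6 s pseudo-trial", {
  set.seed(26)
  rec <- make_recording(stim_events(numeric(0)), duration = 30)
  ep <- data.frame(start = 5, end = 17)
  segs <- extract_baseline_segments(rec, ep, stim_duration = 4.6, n_target = 10)
  expect_equal(length(segs), 2)  # one pre + one post
})

test_that("baseline pairs never exceed stimulation pairs", {
  set.seed(27)
  cfg <- tiny_config(seed = 4)
  rec <- generate_session(cfg)
  ep <- find_baseline_epochs(rec$events, ncol(rec$signals) / rec$sampling_rate)
  segs <- extract_baseline_segments(rec, ep)
  expect_lte(length(segs) / 2, nrow(rec$events))
})

test_that("detrending removes a pure line exactly and is idempotent", {
  n <- 200
  tt <- seq_len(n)
  seg <- list(samples = rbind(3 + 2 * tt, sin(2 * pi * tt / 50) + 0.3 * tt),
              role = "pre", condition = "stimulation", pair_id = 1, group_id = 0)
  out <- detrend_and_center(seg)
  expect_lt(max(abs(out$samples[1, ])), 1e-9)
  # line + sinusoid: result equals sinusoid minus its own least-squares line
  s <- sin(2 * pi * tt / 50)
  fit <- lm(s ~ tt)
  expect_equal(out$samples[2, ], unname(residuals(fit)), tolerance = 1e-9)
  twice <- detrend_and_center(out)
  expect_equal(twice$samples, out$samples, tolerance = 1e-12)
})

test_that("an injected decaying deflection is flagged, clean channels are not", {
  set.seed(28)
  cfg <- tiny_config(seed = 9, n_channels = 8, artifact_channels = "E07",
                     n_trials = 20)
  rec <- generate_session(cfg)
  segs <- extract_stim_segments(rec)
  mask <- detect_artifact_channels(segs)
  expect_false(mask$valid[["E07"]])
  # criterion 1 runs at family-wise alpha = 0.05: allow at most one
  # chance flag among the seven clean channels
  expect_lte(sum(!mask$valid[setdiff(names(mask$valid), "E07")]), 1)
})

test_that("artifact detection false-positive rate stays low on clean sessions", {
  flagged <- vapply(1:6, function(s) {
    rec <- generate_session(tiny_config(seed = 100 + s, n_trials = 15))
    segs <- suppressWarnings(extract_stim_segments(rec))
    sum(!detect_artifact_channels(segs)$valid)
  }, numeric(1))
  # 36 channel decisions in total; allow at most a couple of false flags
  expect_lte(sum(flagged), 2)
})

test_that("an all-zero channel is not flagged as artifact", {
  set.seed(29)
  rec <- make_recording(stim_events(seq(20, 77, by = 3)), duration = 100,
                        signal_fn = function(nch, n) {
                          m <- matrix(rnorm(nch * n), nch, n)
                          m[3, ] <- 0
                          m
                        })
  segs <- extract_stim_segments(rec)
  mask <- detect_artifact_channels(segs)
  expect_true(mask$valid[["E03"]])
})

test_that("common average over valid non-stimulation channels becomes zero", {
  set.seed(30)
  seg <- list(samples = matrix(rnorm(5 * 100), 5, 100,
                               dimnames = list(sprintf("E%02d", 1:5), NULL)),
              role = "pre", condition = "stimulation", pair_id = 1, group_id = 0)
  out <- common_average_rereference(list(seg), mask = NULL,
                                    stim_channels = c("E01", "E02"))[[1]]
  expect_lt(max(abs(colMeans(out$samples[c("E03", "E04", "E05"), ]))), 1e-12)
})

test_that("two non-stimulating channels become +/- half their difference", {
  seg <- list(samples = matrix(c(5, 1), 2, 10,
                               dimnames = list(c("E01", "E02"), NULL)),
              role = "pre", condition = "stimulation", pair_id = 1, group_id = 0)
  out <- common_average_rereference(list(seg))[[1]]
  expect_equal(unname(out$samples[1, ]), rep(2, 10))
  expect_equal(unname(out$samples[2, ]), rep(-2, 10))
})

test_that("stimulation channels receive the average without contributing", {
  vals <- c(10, 2, 4)  # E01 stimulating, common average = mean(2, 4) = 3
  seg <- list(samples = matrix(vals, 3, 8,
                               dimnames = list(c("E01", "E02", "E03"), NULL)),
              role = "pre", condition = "stimulation", pair_id = 1, group_id = 0)
  out <- common_average_rereference(list(seg), stim_channels = "E01")[[1]]
  expect_equal(unname(out$samples[, 1]), vals - 3)
})

test_that("fewer than two valid non-stimulation channels is an error", {
  seg <- list(samples = matrix(1, 2, 4, dimnames = list(c("E01", "E02"), NULL)),
              role = "pre", condition = "stimulation", pair_id = 1, group_id = 0)
  expect_error(common_average_rereference(list(seg), stim_channels = "E01"),
               ">= 2 valid")
})
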