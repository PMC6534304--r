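#' Energy-based voice activity detection over patient material
#'
#' Frame-level RMS intensity (10 ms non-overlapping frames, in dB) is
#' computed per patient turn; frames quieter than the turn's 95th-percentile
#' intensity minus `intensity_threshold` dB are silent. The frame grid bounds
#' every boundary error by one hop, so detected interval edges are exact to
#' 10 ms. Runs of silence of at least
#' `pause_min` s become pauses and runs of voicing of at least `speech_min` s
#' become speech segments; shorter runs are merged into the surrounding
#' opposite state (silence first, then speech), so e.g. a 0.2 s gap does not
#' break a speech segment and an isolated 0.4 s burst is not counted as
#' speech. All intervals are reported on the concatenated patient-material
#' timeline.
#'
#' @param track a `patient_track`
#' @param pause_min minimum pause duration in seconds
#' @param speech_min minimum speech-segment duration in seconds
#' @param intensity_threshold silence threshold in dB below the turn's
#'   95th-percentile intensity
#' @param frame,hop analysis window and hop in seconds
#' @return an object of class `segment_set`: `pauses` and `speech` interval
#'   matrices (start, end in seconds), `total_time`
#' @export
detect_segments <- function(track, pause_min = 0.25, speech_min = 0.5,
                            intensity_threshold = 25,
                            frame = 0.010, hop = 0.010) {
  stopifnot(inherits(track, "patient_track"))
  fs <- track$rate
  frame_n <- round(frame * fs); hop_n <- round(hop * fs)
  offset <- 0
  pauses <- list(); speech <- list()
  for (x in track$utterances) {
    dur <- length(x) / fs
    iv <- utterance_intervals(x, fs, frame_n, hop_n, pause_min, speech_min,
                              intensity_threshold)
    if (nrow(iv$pauses)) pauses[[length(pauses) + 1L]] <- iv$pauses + offset
    if (nrow(iv$speech)) speech[[length(speech) + 1L]] <- iv$speech + offset
    offset <- offset + dur
  }
  p <- if (length(pauses)) do.call(rbind, pauses) else matrix(0, 0, 2)
  s <- if (length(speech)) do.call(rbind, speech) else matrix(0, 0, 2)
  colnames(p) <- colnames(s) <- c("start", "end")
  if (nrow(s) == 0)
    warning("no speech segments detected in patient material")
  structure(list(pauses = p, speech = s,
                 total_time = track$total_turn_time),
            class = "segment_set")
}

## VAD state machine for one utterance; returns interval matrices in seconds
utterance_intervals <- function(x, fs, frame_n, hop_n, pause_min, speech_min,
                                intensity_threshold) {
  none <- matrix(0, 0, 2)
  if (length(x) < frame_n) return(list(pauses = none, speech = none))
  starts <- frame_starts(length(x), frame_n, hop_n)
  rms <- cpp_frame_rms(x, starts, frame_n)
  db <- 20 * log10(rms + 1e-10)
  thr <- as.numeric(quantile(db, 0.95)) - intensity_threshold
  voiced <- db >= thr & rms > 1e-7
  if (!any(voiced)) return(list(pauses = none, speech = none))
  hop_s <- hop_n / fs
  # pass 1: short silence runs join the surrounding speech
  voiced <- absorb_short_runs(voiced, FALSE, pause_min / hop_s)
  # pass 2: short speech runs are discarded into silence
  voiced <- absorb_short_runs(voiced, TRUE, speech_min / hop_s)
  r <- rle(voiced)
  ends_f <- cumsum(r$lengths); starts_f <- ends_f - r$lengths + 1L
  centre <- (starts - 1) / fs + frame_n / fs / 2
  dur <- length(x) / fs
  t0 <- ifelse(starts_f == 1L, 0, centre[starts_f] - hop_s / 2)
  t1 <- ifelse(ends_f == length(voiced), dur, centre[ends_f] + hop_s / 2)
  keep_p <- !r$values & (t1 - t0) >= pause_min - 1e-9
  keep_s <- r$values & (t1 - t0) >= speech_min - 1e-9
  list(pauses = cbind(t0[keep_p], t1[keep_p]),
       speech = cbind(t0[keep_s], t1[keep_s]))
}

absorb_short_runs <- function(state, value, min_frames) {
  r <- rle(state)
  short <- r$values == value & r$lengths < min_frames - 1e-9
  # runs at the signal edges keep their state in the silence pass
  if (identical(value, FALSE)) {
    short[1] <- FALSE
    short[length(short)] <- FALSE
  }
  r$values[short] <- !value
  inverse.rle(r)
}

#' Speech/silence timing statistics of patient material
#'
#' Computes the descriptive speech-silence feature block from a
#' [detect_segments()] result: the mean response time, maximum/mean/SD of
#' pause and speech-segment durations, duration ratios against the patient's
#' total turn time, the pause rate, and the mean/SD/variance of "long" speech
#' segments (at least `long_min` s, which excludes filler-like short
#' vocalisations). SDs and variances use the population convention. Empty
#' duration lists yield 0 for the affected statistics (with a warning) so the
#' feature vector stays complete.
#'
#' @param seg a `segment_set` from [detect_segments()]
#' @param track the `patient_track` the segments came from (supplies the
#'   total-turn-time denominator and response latencies)
#' @param long_min threshold for the filler-excluding statistics, seconds
#' @return named numeric vector of 16 candidate statistics (class
#'   `segmental_features`)
#' @export
segmental_features <- function(seg, track, long_min = 0.8) {
  stopifnot(inherits(seg, "segment_set"), inherits(track, "patient_track"))
  out <- segmental_stats(seg$pauses[, 2] - seg$pauses[, 1],
                         seg$speech[, 2] - seg$speech[, 1],
                         track$response_latencies,
                         track$total_turn_time, long_min)
  class(out) <- c("segmental_features", class(out))
  out
}

## arithmetic core shared with the window-level extractor
segmental_stats <- function(p, s, lat, total, long_min = 0.8) {
  lat <- lat[is.finite(lat)]
  if (length(p) == 0 && length(s) > 0)
    warning("no pauses detected; pause statistics set to 0")
  long <- s[s >= long_min - 1e-9]
  c(mean_response_time = mean0(lat),
    max_pause = max0(p), mean_pause = mean0(p), std_pause = pop_sd(p),
    max_speech = max0(s), mean_speech = mean0(s), std_speech = pop_sd(s),
    ratio_max_pause_total = max0(p) / total,
    ratio_max_speech_total = max0(s) / total,
    ratio_max_speech_max_pause =
      if (length(p) && length(s)) max(s) / max(p) else 0,
    ratio_total_pause_total = sum(p) / total,
    ratio_total_speech_total = sum(s) / total,
    ratio_pause_count_total = length(p) / total,
    mean_long_speech = mean0(long), std_long_speech = pop_sd(long),
    var_long_speech = pop_var(long))
}

#' Partition patient material into fixed-length windows
#'
#' Slices the concatenated patient material of a recording into consecutive
#' non-overlapping windows of `window` seconds (turns are split at window
#' boundaries where needed). A final partial window shorter than `min_last`
#' seconds is merged into the previous window; if it is the only window it is
#' kept. Each window is a `patient_track` carrying the source recording's
#' `group_id`, and the latency of a turn is assigned to the window in which
#' the turn starts.
#'
#' @param track a `patient_track`
#' @param window window length in seconds (default 60)
#' @param min_last minimum length of the final partial window in seconds
#' @return list of `patient_track` windows
#' @export
segment_into_minutes <- function(track, window = 60, min_last = 30) {
  stopifnot(inherits(track, "patient_track"), track$total_turn_time > 0)
  fs <- track$rate
  win_n <- round(window * fs)
  pieces <- list()   # per window: list of (utt index, from, to, latency)
  cur <- list(); cur_n <- 0L
  flush <- function() {
    if (length(cur)) pieces[[length(pieces) + 1L]] <<- cur
    cur <<- list(); cur_n <<- 0L
  }
  for (u in seq_along(track$utterances)) {
    n <- length(track$utterances[[u]])
    from <- 1L
    first_piece <- TRUE
    while (from <= n) {
      room <- win_n - cur_n
      take <- min(n - from + 1L, room)
      cur[[length(cur) + 1L]] <- list(
        u = u, from = from, to = from + take - 1L,
        latency = if (first_piece) track$response_latencies[u] else NA_real_)
      cur_n <- cur_n + take
      from <- from + take
      first_piece <- FALSE
      if (cur_n >= win_n) flush()
    }
  }
  if (cur_n > 0) {
    if (cur_n < round(min_last * fs) && length(pieces) > 0) {
      last <- pieces[[length(pieces)]]
      pieces[[length(pieces)]] <- c(last, cur)
    } else flush()
  }
  lapply(pieces, function(ps) {
    utts <- lapply(ps, function(p) track$utterances[[p$u]][p$from:p$to])
    lats <- vapply(ps, function(p) p$latency, 0)
    w <- patient_track_from_utterances(utts, fs, latencies = lats,
                                       group_id = track$group_id)
    attr(w, "piece_spec") <- ps
    w
  })
}
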