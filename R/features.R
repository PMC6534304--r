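#' Analysis configuration
#'
#' Collects every tunable parameter of the feature extractors in one list so
#' a run is fully described by (config, seed). Values not supplied keep the
#' package defaults.
#'
#' @param ... named overrides of the defaults
#' @return a `voc_config` list
#' @export
voc_config <- function(...) {
  cfg <- list(
    target_rate = 16000,
    # speech/silence block
    pause_min = 0.25, speech_min = 0.5, long_min = 0.8,
    intensity_threshold_db = 25,
    vad_frame_ms = 10, vad_hop_ms = 10,
    # phonation block
    f0_min = 75, f0_max = 500, voicing_threshold = 0.45,
    break_min_ms = 16,
    # spectral block
    frame_ms = 25, hop_ms = 10, n_mels = 26, n_keep = 13,
    preemphasis = 0.97,
    scalarize = TRUE,
    # the 16th segmental candidate dropped to obtain the 15-feature block
    segmental_drop = "ratio_max_speech_total",
    # second-scenario windowing
    window = 60, min_last = 30)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "voc_config")
}

segmental_candidates <- c(
  "mean_response_time", "max_pause", "mean_pause", "std_pause",
  "max_speech", "mean_speech", "std_speech",
  "ratio_max_pause_total", "ratio_max_speech_total",
  "ratio_max_speech_max_pause", "ratio_total_pause_total",
  "ratio_total_speech_total", "ratio_pause_count_total",
  "mean_long_speech", "std_long_speech", "var_long_speech")

#' Canonical feature names
#'
#' The frozen column order of the acoustic feature vector: the speech/silence
#' block (15 by default), the 21 phonation statistics and the 15 spectral
#' descriptors (51 in total under the default configuration).
#'
#' @param config a [voc_config()]
#' @return character vector of feature names
#' @export
feature_names <- function(config = voc_config()) {
  seg <- setdiff(segmental_candidates, config$segmental_drop)
  phon <- paste0(rep(c("f0", "hnr", "nhr", "shimmer", "jitter", "nvb", "dvb"),
                     each = 3), c("_mean", "_std", "_var"))
  spec <- paste0(rep(c("mfcc", "fbank", "ssc"), each = 5),
                 c("_mean", "_std", "_min", "_max", "_var"))
  c(seg, phon, spec)
}

## full per-utterance analysis record (internal)
utt_analysis <- function(x, fs, cfg) {
  dur <- length(x) / fs
  iv <- utterance_intervals(x, fs, round(cfg$vad_frame_ms / 1000 * fs),
                            round(cfg$vad_hop_ms / 1000 * fs),
                            cfg$pause_min, cfg$speech_min,
                            cfg$intensity_threshold_db)
  phon <- phonation_measures(x, fs, cfg$f0_min, cfg$f0_max,
                             cfg$voicing_threshold, cfg$break_min_ms / 1000)
  aw <- NULL
  if (length(x) >= round(cfg$frame_ms / 1000 * fs)) {
    sp <- frame_spectra(x, frame = cfg$frame_ms / 1000,
                        hop = cfg$hop_ms / 1000, n_mels = cfg$n_mels,
                        n_keep = cfg$n_keep, preemphasis = cfg$preemphasis,
                        rate = fs)
    aw <- awsc(sp, dur)
  }
  list(dur = dur,
       pause_dur = iv$pauses[, 2] - iv$pauses[, 1],
       speech_dur = iv$speech[, 2] - iv$speech[, 1],
       phon = phon, awsc = aw)
}

## combine per-utterance analyses into one 51-feature row
aggregate_analyses <- function(analyses, latencies, total_time, cfg) {
  seg <- segmental_stats(
    unlist(lapply(analyses, `[[`, "pause_dur")),
    unlist(lapply(analyses, `[[`, "speech_dur")),
    latencies, total_time, cfg$long_min)
  phon <- summarize_phonation(lapply(analyses, `[[`, "phon"))
  aws <- Filter(Negate(is.null), lapply(analyses, `[[`, "awsc"))
  spec <- if (length(aws)) spectral_features(aws, cfg$scalarize)
          else {
            warning("no utterance was long enough for spectral analysis")
            setNames(numeric(15), paste0(rep(c("mfcc", "fbank", "ssc"),
                                             each = 5),
                                         c("_mean", "_std", "_min",
                                           "_max", "_var")))
          }
  row <- c(unclass(seg), unclass(phon), unclass(spec))
  row[feature_names(cfg)]
}

#' Extract the acoustic feature vector of one recording
#'
#' Runs the three feature blocks over a patient track and returns one named
#' feature row (scenario 1: one row per recording).
#'
#' @param track a `patient_track`
#' @param config a [voc_config()]
#' @return named numeric vector of features
#' @export
extract_track_features <- function(track, config = voc_config()) {
  stopifnot(inherits(track, "patient_track"))
  analyses <- lapply(track$utterances, utt_analysis, fs = track$rate,
                     cfg = config)
  aggregate_analyses(analyses, track$response_latencies,
                     track$total_turn_time, config)
}

#' Extract per-window feature vectors of one recording
#'
#' Slices the patient material into fixed windows (see
#' [segment_into_minutes()]) and extracts the feature vector of each window
#' (scenario 2: one row per one-minute segment). Analyses of turns that are
#' not split by a window boundary are shared with [extract_track_features()]
#' callers via the optional cache argument.
#'
#' @param track a `patient_track`
#' @param config a [voc_config()]
#' @param cache optional list of per-utterance analyses of `track` (internal)
#' @return matrix of feature rows (one per window)
#' @export
extract_window_features <- function(track, config = voc_config(),
                                    cache = NULL) {
  wins <- segment_into_minutes(track, config$window, config$min_last)
  fs <- track$rate
  rows <- lapply(wins, function(wtr) {
    ps <- attr(wtr, "piece_spec")
    analyses <- lapply(seq_along(ps), function(i) {
      p <- ps[[i]]
      whole <- p$from == 1L && p$to == length(track$utterances[[p$u]])
      if (whole && !is.null(cache)) cache[[p$u]]
      else utt_analysis(wtr$utterances[[i]], fs, config)
    })
    aggregate_analyses(analyses, wtr$response_latencies,
                       wtr$total_turn_time, config)
  })
  do.call(rbind, rows)
}

#' Assemble a feature table
#'
#' @param rows numeric matrix (samples x features) with column names
#' @param label class label per row ("FMD" or "ND")
#' @param group_id patient/recording identifier per row
#' @return a `voc_features` data frame: `label`, `group_id`, then features
#' @export
feature_table <- function(rows, label, group_id) {
  rows <- as.matrix(rows)
  stopifnot(nrow(rows) == length(label), nrow(rows) == length(group_id))
  tab <- data.frame(label = factor(label, levels = c("FMD", "ND")),
                    group_id = as.character(group_id),
                    rows, check.names = FALSE, stringsAsFactors = FALSE)
  attr(tab, "feature_cols") <- colnames(rows)
  class(tab) <- c("voc_features", "data.frame")
  tab
}

#' Feature column names of a feature table
#' @param tab a `voc_features` data frame
#' @export
feature_columns <- function(tab) {
  attr(tab, "feature_cols") %||% setdiff(names(tab), c("label", "group_id"))
}

#' @export
print.voc_features <- function(x, ...) {
  cat(sprintf("<voc_features> %d samples x %d features (%s)\n",
              nrow(x), length(feature_columns(x)),
              paste(sprintf("%s: %d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract a feature table from an audio + annotation manifest
#'
#' @param manifest data frame with columns `wav`, `annotation`, `label`,
#'   `group_id` (annotation files may be TSV or Praat TextGrid)
#' @param scenario "recordings" (one row per recording) or "segments"
#'   (one row per one-minute window)
#' @param config a [voc_config()]
#' @return a `voc_features` table; recordings that fail to process are
#'   dropped with a warning
#' @export
extract_features <- function(manifest, scenario = c("recordings", "segments"),
                             config = voc_config()) {
  scenario <- match.arg(scenario)
  if (NROW(manifest) == 0) stop("empty manifest")
  rows <- list(); labs <- character(0); gids <- character(0)
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      w <- load_audio(manifest$wav[i], config$target_rate)
      ann <- if (grepl("\\.textgrid$", manifest$annotation[i],
                       ignore.case = TRUE))
        read_textgrid(manifest$annotation[i])
      else read_turns(manifest$annotation[i])
      track <- extract_patient_track(w, ann, group_id = manifest$group_id[i])
      if (scenario == "recordings")
        matrix(extract_track_features(track, config), nrow = 1,
               dimnames = list(NULL, feature_names(config)))
      else extract_window_features(track, config)
    }, error = function(e) {
      warning("skipping ", manifest$wav[i], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- res
    labs <- c(labs, rep(as.character(manifest$label[i]), nrow(res)))
    gids <- c(gids, rep(as.character(manifest$group_id[i]), nrow(res)))
  }
  if (length(rows) == 0) stop("no recording in the manifest could be processed")
  feature_table(do.call(rbind, rows), labs, gids)
}
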