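#' Voice specification for the source-filter synthesizer
#'
#' Ground-truth phonation parameters of one synthetic speaker: fundamental
#' frequency, cycle-to-cycle period and amplitude perturbation, target
#' harmonics-to-noise ratio, voice-break rate and the formant resonators the
#' glottal pulse train is shaped with.
#'
#' @param f0 fundamental frequency in Hz (75-400)
#' @param jitter_sigma SD of the per-cycle period perturbation, as a fraction
#'   of the period
#' @param shimmer_sigma SD of the per-cycle amplitude perturbation, as a
#'   fraction of the amplitude
#' @param target_hnr periodic-to-noise power ratio in dB (`Inf` = noiseless)
#' @param break_rate voice breaks per second
#' @param break_duration (min, max) break length in seconds
#' @param formants list of (centre Hz, bandwidth Hz) resonators
#' @return a `voice_spec`
#' @export
voice_spec <- function(f0 = 200, jitter_sigma = 0.01, shimmer_sigma = 0.05,
                       target_hnr = 20, break_rate = 0,
                       break_duration = c(0.03, 0.12),
                       formants = list(c(700, 130), c(1220, 160),
                                       c(2600, 250))) {
  stopifnot(f0 >= 75, f0 <= 400, jitter_sigma >= 0, shimmer_sigma >= 0,
            break_rate >= 0, length(break_duration) == 2)
  structure(list(f0 = f0, jitter_sigma = jitter_sigma,
                 shimmer_sigma = shimmer_sigma, target_hnr = target_hnr,
                 break_rate = break_rate, break_duration = break_duration,
                 formants = formants),
            class = "voice_spec")
}

#' Synthesize a vowel-like voiced utterance
#'
#' Source-filter synthesis: a glottal pulse train with per-cycle period
#' perturbation N(0, jitter_sigma * T0) and amplitude perturbation
#' N(0, shimmer_sigma), optionally interrupted by silent voice breaks, is
#' passed through second-order resonators at the formant frequencies;
#' white noise is added so the periodic-to-noise power ratio equals
#' `target_hnr`. Pulses are placed with sub-sample precision (linear
#' two-tap interpolation), so the true pulse instants in the returned
#' ground truth are exact.
#'
#' @param spec a [voice_spec()]
#' @param duration utterance length in seconds (> 3 periods)
#' @param rate sampling rate in Hz
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched
#' @return list with `waveform`, `pulses` (true times/amplitudes), `breaks`
#'   (data frame of inserted gaps)
#' @export
synthesize_voice <- function(spec, duration, rate = 16000, seed = NULL) {
  stopifnot(inherits(spec, "voice_spec"), duration > 3 / spec$f0)
  run <- function() synth_voice_impl(spec, duration, rate)
  if (is.null(seed)) run() else with_seed(seed, run())
}

synth_voice_impl <- function(spec, duration, rate) {
  T0 <- 1 / spec$f0
  n_p <- ceiling(duration / T0) + 2L
  periods <- T0 * (1 + rnorm(n_p, 0, spec$jitter_sigma))
  periods <- pmin(pmax(periods, 0.5 * T0), 1.75 * T0)
  times <- T0 / 2 + cumsum(c(0, periods[-n_p]))
  keep <- times < duration - T0 / 4
  times <- times[keep]
  amps <- pmax(1 + rnorm(length(times), 0, spec$shimmer_sigma), 0.05)
  brk <- data.frame(start = numeric(0), duration = numeric(0))
  if (spec$break_rate > 0) {
    nb <- rpois(1, spec$break_rate * duration)
    if (nb > 0) {
      bd <- runif(nb, spec$break_duration[1], spec$break_duration[2])
      if (sum(bd) >= duration)
        stop("infeasible voice spec: break gaps exceed the duration")
      bs <- runif(nb, 0.05 * duration, max(0.05 * duration,
                                           0.95 * duration - max(bd)))
      brk <- data.frame(start = bs, duration = bd)
      in_break <- rep(FALSE, length(times))
      for (k in seq_len(nb))
        in_break <- in_break | (times >= bs[k] & times < bs[k] + bd[k])
      times <- times[!in_break]; amps <- amps[!in_break]
    }
  }
  n <- round(duration * rate)
  pad <- 20L
  e <- numeric(n + 2L * pad)
  pos <- times * rate + 1 + pad
  i0 <- round(pos); frac <- pos - i0
  # windowed-sinc fractional placement: band-limited impulses keep the true
  # instants (and amplitudes) on the waveform to sub-sample precision
  taps <- -16:16
  bw <- 0.42 + 0.5 * cos(pi * taps / 16.5) + 0.08 * cos(2 * pi * taps / 16.5)
  for (k in seq_along(taps)) {
    arg <- taps[k] - frac
    v <- ifelse(abs(arg) < 1e-12, 1, sin(pi * arg) / (pi * arg))
    ii <- i0 + taps[k]
    e[ii] <- e[ii] + amps * v * bw[k]
  }
  e <- e[(pad + 1L):(pad + n)]
  sos <- do.call(rbind, lapply(spec$formants, function(fm) {
    r <- exp(-pi * fm[2] / rate); th <- 2 * pi * fm[1] / rate
    c(1, 0, 0, -2 * r * cos(th), r * r)
  }))
  y <- cpp_sos_filter(e, sos)
  m <- max(abs(y))
  if (m > 0) y <- y * (0.5 / m)
  if (is.finite(spec$target_hnr)) {
    sd_n <- sqrt(mean(y^2) / 10^(spec$target_hnr / 10))
    y <- y + rnorm(n, 0, sd_n)
    m2 <- max(abs(y))
    if (m2 > 0.99) y <- y * (0.99 / m2)
  }
  list(waveform = waveform(y, rate),
       pulses = list(times = times, amplitudes = amps),
       breaks = brk)
}

#' Dialogue specification
#'
#' Conversation-level parameters of one synthetic patient: turn-taking
#' latencies, utterance lengths, within-turn pausing and the total patient
#' talk-time budget.
#'
#' @param class_label "FMD" or "ND"
#' @param response_latency_dist c(mean, sd) of turn-start latencies, seconds
#' @param utterance_length_dist c(mean, sd) of utterance lengths, seconds
#' @param within_turn_pause_rate expected pauses per second of talk
#' @param pause_duration_dist c(mean, sd) of within-turn pauses, seconds
#' @param patient_talk_total target total patient turn time, minutes
#' @param n_turns optional fixed number of patient turns (overrides the
#'   talk-time budget)
#' @param ambient_snr_db recording-room noise floor: speech-to-ambient power
#'   ratio in dB over the whole recording (`Inf` = clean)
#' @param spectral_tilt first-order microphone/room coloration coefficient
#'   applied to the whole recording (0 = flat)
#' @return a `dialogue_spec`
#' @export
dialogue_spec <- function(class_label = c("FMD", "ND"),
                          response_latency_dist = c(0.8, 0.4),
                          utterance_length_dist = c(3.0, 1.5),
                          within_turn_pause_rate = 0.15,
                          pause_duration_dist = c(0.6, 0.25),
                          patient_talk_total = 8,
                          n_turns = NULL,
                          ambient_snr_db = Inf,
                          spectral_tilt = 0) {
  class_label <- match.arg(class_label)
  stopifnot(response_latency_dist[1] > 0, utterance_length_dist[1] > 0,
            pause_duration_dist[1] > 0, patient_talk_total > 0,
            within_turn_pause_rate >= 0, abs(spectral_tilt) < 0.9)
  structure(list(class_label = class_label,
                 response_latency_dist = response_latency_dist,
                 utterance_length_dist = utterance_length_dist,
                 within_turn_pause_rate = within_turn_pause_rate,
                 pause_duration_dist = pause_duration_dist,
                 patient_talk_total = patient_talk_total,
                 n_turns = n_turns,
                 ambient_snr_db = ambient_snr_db,
                 spectral_tilt = spectral_tilt),
            class = "dialogue_spec")
}

#' Synthesize one doctor-patient conversation
#'
#' Alternates synthetic doctor questions and patient answers. Patient turns
#' are sequences of voiced utterances separated by within-turn pauses
#' (truncated at the 0.25 s detectability threshold); turn-start latencies
#' follow the dialogue spec. Generation stops when the accumulated patient
#' turn time reaches the talk-time budget (or after `n_turns` turns when
#' fixed). The ground-truth log records every utterance, pause, latency and
#' the per-utterance pulse/break truth.
#'
#' @param d a [dialogue_spec()]
#' @param v the patient's [voice_spec()]
#' @param seed integer seed (one stream drives the whole conversation)
#' @param doctor_voice the interviewer's [voice_spec()]
#' @param rate sampling rate in Hz
#' @return list with `waveform`, `annotation` (a `turn_annotation`) and
#'   `truth` (utterance/pause/latency tables and totals)
#' @export
synthesize_dialogue <- function(d, v, seed = 1,
                                doctor_voice = voice_spec(
                                  f0 = 110, jitter_sigma = 0.008,
                                  shimmer_sigma = 0.04, target_hnr = 22),
                                rate = 16000) {
  stopifnot(inherits(d, "dialogue_spec"), inherits(v, "voice_spec"))
  with_seed(seed, synth_dialogue_impl(d, v, doctor_voice, rate))
}

synth_dialogue_impl <- function(d, v, doctor_voice, rate) {
  target_s <- d$patient_talk_total * 60
  chunks <- list()          # audio pieces in order
  t <- 0; talk <- 0; n_turns_done <- 0L
  ann <- list()
  utt_log <- list(); pause_log <- list(); lat_log <- numeric(0)
  add <- function(x) chunks[[length(chunks) + 1L]] <<- x
  more <- function() {
    if (!is.null(d$n_turns)) n_turns_done < d$n_turns else talk < target_s
  }
  # slow within-session drift of conversational behaviour (AR(1) on the log
  # scale): hesitancy drives pausing and response latency, verbosity drives
  # utterance length.  Real history-taking is nonstationary, so one-minute
  # segments vary around the speaker's session average.
  rho <- 0.9
  sd_h <- 0.5; sd_v <- 0.35
  g_h <- rnorm(1, 0, sd_h); g_v <- rnorm(1, 0, sd_v)
  innov <- sqrt(1 - rho^2)
  while (more()) {
    g_h <- rho * g_h + rnorm(1, 0, sd_h * innov)
    g_v <- rho * g_v + rnorm(1, 0, sd_v * innov)
    # doctor question
    ddur <- runif(1, 1.5, 4)
    doc <- synth_voice_impl(doctor_voice, ddur, rate)
    dn <- length(doc$waveform$samples)
    add(doc$waveform$samples)
    ann[[length(ann) + 1L]] <- c(t, t + dn / rate, NA) # speaker name below
    names(ann)[length(ann)] <- "doctor"
    t <- t + dn / rate
    # response latency
    lat <- rnorm_trunc(1, d$response_latency_dist[1] * exp(0.7 * g_h),
                       d$response_latency_dist[2], 0.05, 10)
    add(numeric(round(lat * rate)))
    t <- t + round(lat * rate) / rate
    lat_log <- c(lat_log, lat)
    # patient turn
    turn_start <- t
    utts <- 1L + rpois(1, 2)
    turn_audio <- list()
    for (k in seq_len(utts)) {
      udur <- rnorm_trunc(1, d$utterance_length_dist[1] * exp(g_v),
                          d$utterance_length_dist[2], 0.6,
                          d$utterance_length_dist[1] +
                            4 * d$utterance_length_dist[2])
      uv <- synth_voice_impl(v, udur, rate)
      un <- length(uv$waveform$samples)
      utt_log[[length(utt_log) + 1L]] <- list(
        start = t, end = t + un / rate,
        n_pulses = length(uv$pulses$times),
        n_breaks = nrow(uv$breaks),
        break_time = sum(uv$breaks$duration))
      turn_audio[[length(turn_audio) + 1L]] <- uv$waveform$samples
      t <- t + un / rate
      talk <- talk + un / rate
      if (k < utts &&
          runif(1) < min(0.95, d$within_turn_pause_rate * exp(g_h) * udur)) {
        pdur <- rnorm_trunc(1, d$pause_duration_dist[1] * exp(0.5 * g_h),
                            d$pause_duration_dist[2], 0.25, 6)
        pn <- round(pdur * rate)
        pause_log[[length(pause_log) + 1L]] <- c(t, t + pn / rate)
        turn_audio[[length(turn_audio) + 1L]] <- numeric(pn)
        t <- t + pn / rate
        talk <- talk + pn / rate
      }
      if (is.null(d$n_turns) && talk >= target_s) break
    }
    add(unlist(turn_audio))
    ann[[length(ann) + 1L]] <- c(turn_start, t, NA)
    names(ann)[length(ann)] <- "patient"
    n_turns_done <- n_turns_done + 1L
    # short inter-turn settling gap before the next question
    gap <- runif(1, 0.3, 0.8)
    add(numeric(round(gap * rate)))
    t <- t + round(gap * rate) / rate
  }
  x <- unlist(chunks)
  # recording-level nuisance: microphone/room coloration and ambient noise,
  # both class-neutral
  if (abs(d$spectral_tilt %||% 0) > 0)
    x <- cpp_sos_filter(x, matrix(c(1, -d$spectral_tilt, 0, 0, 0), 1))
  amb <- d$ambient_snr_db %||% Inf
  if (is.finite(amb)) {
    loud <- abs(x) > 1e-3
    spw <- if (any(loud)) mean(x[loud]^2) else mean(x^2)
    x <- x + rnorm(length(x), 0, sqrt(spw / 10^(amb / 10)))
  }
  m <- max(abs(x))
  if (m > 0.99) x <- x * (0.99 / m)
  at <- do.call(rbind, ann)
  annotation <- turn_annotation(data.frame(
    start = round(at[, 1], 6), end = round(at[, 2], 6),
    speaker = names(ann), stringsAsFactors = FALSE))
  truth <- list(
    utterances = do.call(rbind, lapply(utt_log, as.data.frame)),
    pauses = if (length(pause_log))
      do.call(rbind, lapply(pause_log, function(p)
        data.frame(start = p[1], end = p[2])))
    else data.frame(start = numeric(0), end = numeric(0)),
    latencies = lat_log,
    patient_talk_s = talk,
    n_patient_turns = n_turns_done)
  list(waveform = waveform(x, rate), annotation = annotation, truth = truth)
}

## ---- cohort-level defaults --------------------------------------------------

## class-conditional generator parameters; each contrasted entry is
## c(FMD value(s), ND value(s)) and is interpolated towards the pooled
## midpoint by effect_scale (0 = exchangeable classes)
cohort_defaults <- function() {
  list(
    talk_total_min = list(FMD = c(11.5, 6.3), ND = c(6.2, 4.5)),
    utterance_length = list(FMD = c(3.2, 1.6), ND = c(2.3, 1.2)),
    pause_rate = list(FMD = 0.10, ND = 0.24),
    pause_duration = list(FMD = c(0.48, 0.18), ND = c(0.75, 0.30)),
    response_latency = list(FMD = c(0.7, 0.4), ND = c(1.5, 0.8)),
    break_rate = list(FMD = 0.15, ND = 0.55),
    target_hnr = list(FMD = 19, ND = 18),
    # sex mixture (class-neutral, mirrors the near-balanced female share):
    # P(female), then N(mean, sd) per sex
    p_female = 0.57,
    f0_female = c(200, 20),
    f0_male = c(125, 15),
    jitter_sigma = c(0.012, 0.003),
    shimmer_sigma = c(0.05, 0.012),
    break_duration = c(0.03, 0.12),
    ambient_snr = c(38, 3),
    spectral_tilt_sd = 0.15)
}

#' Cohort specification
#'
#' Two-class synthetic cohort mirroring the memory-clinic study structure:
#' `n_per_class` recordings per class with class-conditional talk-time,
#' pausing, utterance-length, voice-break and harmonicity parameters.
#' `effect_scale` interpolates every class contrast towards the pooled
#' midpoint: 0 makes the classes exchangeable in distribution, 1 is the
#' default contrast.
#'
#' @param n_per_class recordings per class (default 15)
#' @param seed master seed; all per-recording substreams derive from it
#' @param effect_scale class-separation multiplier in [0, 1+]
#' @param params class-conditional parameter table (see `cohort_defaults`)
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n_per_class = 15, seed = 1, effect_scale = 1,
                        params = cohort_defaults()) {
  structure(list(n_per_class = n_per_class, seed = seed,
                 effect_scale = effect_scale, params = params),
            class = "cohort_spec")
}

## class value after effect-scale interpolation
scaled_param <- function(params, name, class_label, effect_scale) {
  p <- params[[name]]
  if (!is.list(p)) return(p)                # class-neutral
  mid <- (p$FMD + p$ND) / 2
  mid + effect_scale * (p[[class_label]] - mid)
}

## draw one patient's dialogue + voice specs (uses the current RNG stream)
draw_patient_specs <- function(cs, class_label) {
  pr <- cs$params; es <- cs$effect_scale
  g <- function(nm) scaled_param(pr, nm, class_label, es)
  talk <- rnorm_trunc(1, g("talk_total_min")[1], g("talk_total_min")[2],
                      lower = 1)
  ul <- g("utterance_length")
  ul_mean <- rnorm_trunc(1, ul[1], 0.25 * ul[1], 0.8)
  prate <- rnorm_trunc(1, g("pause_rate"), 0.35 * g("pause_rate"), 0.01)
  pd <- g("pause_duration")
  pd_mean <- rnorm_trunc(1, pd[1], 0.2 * pd[1], 0.3)
  rl <- g("response_latency")
  rl_mean <- rnorm_trunc(1, rl[1], 0.35 * rl[1], 0.1)
  d <- dialogue_spec(class_label = class_label,
                     response_latency_dist = c(rl_mean, rl[2]),
                     utterance_length_dist = c(ul_mean, ul[2]),
                     within_turn_pause_rate = prate,
                     pause_duration_dist = c(pd_mean, pd[2]),
                     patient_talk_total = talk,
                     ambient_snr_db = rnorm_trunc(1, pr$ambient_snr[1],
                                                  pr$ambient_snr[2], 32, 45),
                     spectral_tilt = rnorm_trunc(1, 0, pr$spectral_tilt_sd,
                                                 -0.35, 0.35))
  f0d <- if (runif(1) < pr$p_female) pr$f0_female else pr$f0_male
  v <- voice_spec(
    f0 = rnorm_trunc(1, f0d[1], f0d[2], 95, 320),
    jitter_sigma = rnorm_trunc(1, pr$jitter_sigma[1], pr$jitter_sigma[2],
                               0.002),
    shimmer_sigma = rnorm_trunc(1, pr$shimmer_sigma[1],
                                pr$shimmer_sigma[2], 0.01),
    target_hnr = rnorm_trunc(1, g("target_hnr"), 2.5, 8, 30),
    break_rate = rnorm_trunc(1, g("break_rate"), 0.5 * g("break_rate"),
                             0.01),
    break_duration = pr$break_duration)
  list(dialogue = d, voice = v)
}

## recording roster: id, class, per-recording seed
cohort_roster <- function(cs) {
  ids <- c(sprintf("FMD_%02d", seq_len(cs$n_per_class)),
           sprintf("ND_%02d", seq_len(cs$n_per_class)))
  data.frame(group_id = ids,
             label = rep(c("FMD", "ND"), each = cs$n_per_class),
             seed = vapply(seq_along(ids),
                           function(i) derive_seed(cs$seed, i), 1L),
             stringsAsFactors = FALSE)
}

## synthesize one roster entry (deterministic in its seed)
synth_cohort_recording <- function(cs, roster_row) {
  specs <- with_seed(roster_row$seed,
                     draw_patient_specs(cs, roster_row$label))
  rec <- synthesize_dialogue(specs$dialogue, specs$voice,
                             seed = derive_seed(roster_row$seed, 7919L))
  rec$specs <- specs
  rec$group_id <- roster_row$group_id
  rec$label <- roster_row$label
  rec
}

#' Generate a synthetic two-class cohort on disk
#'
#' Writes one 16 kHz mono PCM-16 WAV, one TSV turn annotation and one
#' ground-truth JSON per recording, plus a cohort manifest CSV. Fully
#' reproducible from the cohort seed.
#'
#' @param cs a [cohort_spec()]
#' @param dir output directory (created if needed)
#' @return the manifest data frame (paths, label, group_id), invisibly
#'   written to `manifest.csv`
#' @export
generate_cohort <- function(cs, dir) {
  stopifnot(inherits(cs, "cohort_spec"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  roster <- cohort_roster(cs)
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    rec <- synth_cohort_recording(cs, roster[i, ])
    base <- file.path(dir, roster$group_id[i])
    write_wav(rec$waveform, rec$waveform$rate, paste0(base, ".wav"))
    ann <- rec$annotation
    writeLines(sprintf("%.6f\t%.6f\t%s", ann$start, ann$end, ann$speaker),
               paste0(base, ".tsv"))
    truth <- rec$truth
    truth$dialogue_spec <- unclass(rec$specs$dialogue)
    truth$voice_spec <- unclass(rec$specs$voice)
    jsonlite::write_json(truth, paste0(base, "_truth.json"),
                         auto_unbox = TRUE, digits = 8)
    data.frame(group_id = roster$group_id[i], label = roster$label[i],
               wav = paste0(base, ".wav"), annotation = paste0(base, ".tsv"),
               truth = paste0(base, "_truth.json"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Extract feature tables from a synthetic cohort without touching disk
#'
#' Streams the cohort: each recording is synthesized, run through patient
#' isolation and feature extraction, then discarded. Scenario-1 rows use the
#' whole recording; scenario-2 rows its one-minute windows (per-turn
#' analyses are shared between the two scenarios).
#'
#' @param cs a [cohort_spec()]
#' @param config a [voc_config()]
#' @param scenarios character subset of c("recordings", "segments")
#' @return list with `recordings` and/or `segments` feature tables and the
#'   per-recording `truth` logs
#' @export
cohort_feature_tables <- function(cs, config = voc_config(),
                                  scenarios = c("recordings", "segments")) {
  roster <- cohort_roster(cs)
  rec_rows <- list(); seg_rows <- list()
  rec_meta <- list(); seg_meta <- list(); truths <- list()
  for (i in seq_len(nrow(roster))) {
    rec <- synth_cohort_recording(cs, roster[i, ])
    track <- extract_patient_track(rec$waveform, rec$annotation,
                                   group_id = rec$group_id)
    cache <- lapply(track$utterances, utt_analysis, fs = track$rate,
                    cfg = config)
    if ("recordings" %in% scenarios) {
      rec_rows[[length(rec_rows) + 1L]] <-
        aggregate_analyses(cache, track$response_latencies,
                           track$total_turn_time, config)
      rec_meta[[length(rec_meta) + 1L]] <-
        c(rec$label, rec$group_id)
    }
    if ("segments" %in% scenarios) {
      m <- extract_window_features(track, config, cache = cache)
      seg_rows[[length(seg_rows) + 1L]] <- m
      seg_meta[[length(seg_meta) + 1L]] <-
        cbind(rep(rec$label, nrow(m)), rep(rec$group_id, nrow(m)))
    }
    truths[[rec$group_id]] <- rec$truth
    rm(rec, track, cache)
  }
  out <- list(truth = truths)
  if (length(rec_rows)) {
    meta <- do.call(rbind, rec_meta)
    out$recordings <- feature_table(do.call(rbind, rec_rows),
                                    meta[, 1], meta[, 2])
  }
  if (length(seg_rows)) {
    meta <- do.call(rbind, seg_meta)
    out$segments <- feature_table(do.call(rbind, seg_rows),
                                  meta[, 1], meta[, 2])
  }
  out
}
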