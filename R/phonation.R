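## ---- pitch-analysis helpers -------------------------------------------------

## one biquad low-pass (Butterworth order 2) as an SOS row; applied twice as
## the anti-alias filter before lag-search decimation
lowpass_sos <- function(W) {
  ba <- signal::butter(2, W)
  matrix(c(ba$b[1], ba$b[2], ba$b[3], ba$a[2], ba$a[3]), nrow = 1)
}

## ---- pitch tracking ---------------------------------------------------------

#' Autocorrelation pitch tracking
#'
#' Per 40 ms frame (10 ms hop), the fundamental period is found as the lag
#' maximising the normalized autocorrelation within [1/f0_max, 1/f0_min].
#' The lag search runs on a low-passed, decimated copy of the signal; the
#' winning lag is then re-evaluated at the full rate with normalized
#' cross-correlation at three neighbouring lags and refined by parabolic
#' interpolation, giving sub-sample period precision and an unbiased voicing
#' strength r. A frame is voiced iff r >= `voicing_threshold`.
#'
#' @param w a [waveform()] (or numeric vector with `rate`)
#' @param f0_min,f0_max pitch search range in Hz
#' @param frame,hop analysis frame length and hop in seconds
#' @param voicing_threshold minimum voicing strength r for a voiced frame
#' @param rate sampling rate, used when `w` is a bare numeric vector
#' @return a `pitch_track`: data frame with per-frame `t` (frame centre, s),
#'   `f0` (Hz, `NA` when unvoiced), `r` (voicing strength), `voiced`;
#'   frame geometry in attributes
#' @export
track_pitch <- function(w, f0_min = 75, f0_max = 500, frame = 0.040,
                        hop = 0.010, voicing_threshold = 0.45, rate = NULL) {
  if (inherits(w, "waveform")) { x <- w$samples; fs <- w$rate }
  else { x <- as.numeric(w); fs <- rate %||% 16000 }
  frame_n <- round(frame * fs); hop_n <- round(hop * fs)
  starts <- frame_starts(length(x), frame_n, hop_n)
  empty <- data.frame(t = numeric(0), f0 = numeric(0), r = numeric(0),
                      voiced = logical(0))
  geom <- function(df) {
    attr(df, "starts") <- starts; attr(df, "frame_n") <- frame_n
    attr(df, "hop_n") <- hop_n; attr(df, "fs") <- fs
    class(df) <- c("pitch_track", "data.frame"); df
  }
  if (length(starts) == 0) return(geom(empty))
  dec <- max(1L, floor(fs / 4000))
  if (dec > 1L) {
    xl <- cpp_sos_filter(x, lowpass_sos(0.8 / dec))
    xl <- cpp_sos_filter(xl, lowpass_sos(0.8 / dec))
    xd <- xl[seq(1L, length(xl), by = dec)]
  } else xd <- x
  fs_d <- fs / dec
  fr_d <- frame_n %/% dec; hp_d <- hop_n %/% dec
  st_d <- (starts - 1L) %/% dec + 1L
  st_d <- pmin(st_d, max(1L, length(xd) - fr_d + 1L))
  lag_lo <- max(2L, floor(fs_d / f0_max))
  lag_hi <- min(fr_d - 2L, ceiling(fs_d / f0_min))
  # candidate lag per frame: parabolically interpolated local ACF maxima
  # under an octave penalty (a non-integer period quantizes differently at
  # the lag and its multiples, so raw grid values cannot be compared)
  cand <- cpp_pitch_candidates(xd, st_d, fr_d, lag_lo, lag_hi, 0.05)
  lag_frac <- cand[1, ]
  # full-rate refinement around the candidate lag (5-point local max)
  refine <- function(lag16, st = starts) {
    r5 <- cpp_xcorr_frames(x, st, frame_n, as.integer(lag16))
    kbest <- max.col(t(r5[2:4, , drop = FALSE]), ties.method = "first") + 1L
    idx <- seq_len(ncol(r5))
    ya <- r5[cbind(kbest - 1L, idx)]
    yb <- r5[cbind(kbest, idx)]
    yc <- r5[cbind(kbest + 1L, idx)]
    den2 <- ya - 2 * yb + yc
    d <- ifelse(den2 < -1e-12, 0.5 * (ya - yc) / den2, 0)
    d <- pmax(pmin(d, 0.5), -0.5)
    list(lag = lag16 + (kbest - 3L) + d,
         r = pmin(pmax(pmax(yb - 0.25 * (ya - yc) * d, yb), 0), 0.9999))
  }
  lag_min16 <- max(2L, floor(fs / f0_max))
  lag16 <- as.integer(round(pmin(pmax(lag_frac * dec, lag_min16),
                                 ceiling(fs / f0_min))))
  # frames without a plausible decimated-rate correlation stay unvoiced and
  # skip the full-rate refinement
  lag_ref <- lag_frac * dec
  r <- pmin(pmax(cand[2, ], 0), 0.9999)
  act <- which(cand[2, ] >= 0.3)
  if (length(act)) {
    cur <- refine(lag16[act], starts[act])
    # octave-down check at the full rate: when the tracker sits on a period
    # multiple, the refined correlation at half the lag is at least as good
    check <- rep(TRUE, length(act))
    for (pass in 1:2) {
      half <- as.integer(round(cur$lag / 2))
      ok <- which(check & half >= lag_min16 & half >= 2L)
      if (length(ok) == 0) break
      alt <- refine(half[ok], starts[act][ok])
      sel <- alt$r >= cur$r[ok] - 0.02
      if (!any(sel)) break
      take <- ok[sel]
      cur$lag[take] <- alt$lag[sel]
      cur$r[take] <- alt$r[sel]
      check <- seq_along(cur$lag) %in% take
    }
    lag_ref[act] <- cur$lag
    r[act] <- cur$r
  }
  rms <- cpp_frame_rms(x, starts, frame_n)
  f0 <- fs / lag_ref
  voiced <- r >= voicing_threshold & rms > 1e-7 &
    f0 >= f0_min * 0.9 & f0 <= f0_max * 1.1
  # kill residual octave jumps: 5-point running median within voiced runs
  if (any(voiced)) {
    rr <- rle(voiced)
    re <- cumsum(rr$lengths); rb <- re - rr$lengths + 1L
    for (k in which(rr$values)) {
      if (rr$lengths[k] >= 3) {
        i <- rb[k]:re[k]
        f0[i] <- stats::runmed(f0[i], k = min(5L, 2L *
                                                (rr$lengths[k] %/% 2L) - 1L))
      }
    }
  }
  df <- data.frame(t = (starts - 1) / fs + frame_n / fs / 2,
                   f0 = ifelse(voiced, f0, NA_real_),
                   r = r, voiced = voiced)
  geom(df)
}

## ---- pulse marking ----------------------------------------------------------

#' Glottal pulse extraction
#'
#' Within each voiced run of the pitch track, one pulse per period is placed
#' at the waveform maximum nearest the predicted pulse instant (predictions
#' advance by the local period); pulse positions are refined to sub-sample
#' precision by parabolic interpolation and periods between consecutive
#' pulses by waveform matching. Pulses whose amplitude falls below a quarter
#' of the run's median amplitude are treated as unvoiced material (the marker
#' otherwise walks straight through short voice breaks snapping to noise
#' peaks) and split their run.
#'
#' @param w a [waveform()] (or numeric vector; the track carries the rate)
#' @param pitch a `pitch_track` from [track_pitch()]
#' @return a `pulse_train`: `times` (s), `amplitudes`, `run` (voiced-run id
#'   per pulse), `periods` (s, between consecutive same-run pulses) and
#'   `period_run` (run id per period)
#' @export
extract_pulses <- function(w, pitch) {
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  fs <- attr(pitch, "fs")
  starts <- attr(pitch, "starts"); frame_n <- attr(pitch, "frame_n")
  times <- numeric(0); amps <- numeric(0); run_id <- integer(0)
  periods <- numeric(0); period_run <- integer(0)
  next_run <- 1L
  if (nrow(pitch) > 0 && any(pitch$voiced)) {
    r <- rle(pitch$voiced)
    ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
    vruns <- which(r$values)
    for (k in seq_along(vruns)) {
      i1 <- begs[vruns[k]]; i2 <- ends[vruns[k]]
      s0 <- starts[i1]; s1 <- min(starts[i2] + frame_n - 1L, length(x))
      per_frame <- fs / pitch$f0[i1:i2]
      centres <- starts[i1:i2] + frame_n / 2
      per <- if (i2 > i1)
        stats::approx(centres, per_frame, xout = s0:s1, rule = 2)$y
      else rep(per_frame[1], s1 - s0 + 1L)
      pm <- cpp_mark_pulses(x, s0, s1, per)
      if (ncol(pm) == 0) next
      keep <- pm[2, ] >= 0.25 * median(pm[2, ])
      # later runs may overlap the previous frame span; keep time monotone
      tt <- (pm[1, ] - 1) / fs
      if (length(times))
        keep <- keep & tt > times[length(times)] + 0.5 * per[1] / fs
      if (!any(keep)) next
      idx <- which(keep)
      # contiguous retained stretches become separate pulse runs
      stretch <- cumsum(c(1L, diff(idx) != 1L))
      for (srun in unique(stretch)) {
        sel <- idx[stretch == srun]
        times <- c(times, tt[sel]); amps <- c(amps, pm[2, sel])
        run_id <- c(run_id, rep(next_run, length(sel)))
        if (length(sel) > 1) {
          pr <- pm[3, sel[-length(sel)]] / fs
          raw <- diff(tt[sel])
          pr[!is.finite(pr)] <- raw[!is.finite(pr)]
          periods <- c(periods, pr)
          period_run <- c(period_run, rep(next_run, length(pr)))
        }
        next_run <- next_run + 1L
      }
    }
  }
  structure(list(times = times, amplitudes = amps, run = run_id,
                 periods = periods, period_run = period_run),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses, %d periods in %d voiced runs\n",
              length(x$times), length(x$periods),
              length(unique(x$run))))
  invisible(x)
}

## ---- voice-quality measures -------------------------------------------------

#' Local jitter in percent
#'
#' 100 x mean absolute difference of consecutive same-run periods, divided by
#' the mean of all periods.
#'
#' @param p a `pulse_train`
#' @return jitter in percent; 0 with a warning when fewer than 2 periods
#' @export
jitter_local <- function(p) {
  if (length(p$periods) < 2) {
    warning("fewer than 2 periods; jitter undefined, recorded as 0")
    return(0)
  }
  ok <- period_valid(p)
  pair <- diff(p$period_run) == 0L & ok[-length(ok)] & ok[-1]
  d <- abs(diff(p$periods))[pair]
  if (length(d) == 0) {
    warning("no consecutive same-run period pairs; jitter recorded as 0")
    return(0)
  }
  100 * mean(d) / mean(p$periods[ok])
}

## periods within a plausible band around the train's median; skipped or
## half cycles from rare tracking glitches are excluded from perturbation
## statistics (the voice-break detector still sees the raw gaps)
period_valid <- function(p) {
  if (length(p$periods) == 0) return(logical(0))
  med <- median(p$periods)
  p$periods >= 0.7 * med & p$periods <= 1.4 * med
}

#' Local shimmer in percent
#'
#' As [jitter_local()] with consecutive pulse amplitudes in place of periods.
#' @param p a `pulse_train`
#' @return shimmer in percent; 0 with a warning when fewer than 2 pulses
#' @export
shimmer_local <- function(p) {
  if (length(p$amplitudes) < 2) {
    warning("fewer than 2 pulses; shimmer undefined, recorded as 0")
    return(0)
  }
  same <- diff(p$run) == 0L
  d <- abs(diff(p$amplitudes))[same]
  # amplitude pairs align 1:1 with the same-run periods; keep valid cycles
  ok <- period_valid(p)
  if (length(d) == length(ok)) d <- d[ok]
  if (length(d) == 0) {
    warning("no consecutive same-run pulse pairs; shimmer recorded as 0")
    return(0)
  }
  100 * mean(d) / mean(p$amplitudes)
}

#' Harmonics-to-noise and noise-to-harmonics ratios
#'
#' Per voiced frame with voicing strength r, the frame harmonicity is
#' 10 log10(r / (1 - r)) dB and its noise counterpart (1 - r) / r, so the
#' two frame quantities satisfy nhr == 10^(-hnr / 10) exactly. HNR and NHR
#' are the means over voiced frames.
#'
#' @param pitch a `pitch_track`
#' @return named numeric vector c(hnr = dB, nhr = ratio); both 0 with a
#'   warning when no frame is voiced
#' @export
harmonicity <- function(pitch) {
  r <- pitch$r[pitch$voiced]
  if (length(r) == 0) {
    warning("no voiced frames; HNR/NHR recorded as 0")
    return(c(hnr = 0, nhr = 0))
  }
  r <- pmin(pmax(r, 1e-4), 0.9999)
  c(hnr = mean(10 * log10(r / (1 - r))), nhr = mean((1 - r) / r))
}

#' Voice breaks
#'
#' A break is an inter-pulse gap longer than `break_min` seconds that also
#' exceeds 1.25 x the utterance's median period (so slow but regular cycles
#' are not counted). The degree of voice breaks is the total break time over
#' the utterance duration.
#'
#' @param p a `pulse_train` over one utterance
#' @param utterance_duration duration of the analysed utterance in seconds
#' @param break_min minimum gap in seconds (default 0.016)
#' @return named numeric vector c(count, degree)
#' @export
voice_breaks <- function(p, utterance_duration, break_min = 0.016) {
  if (length(p$times) < 2) return(c(count = 0, degree = 0))
  gaps <- diff(p$times)
  med_T <- if (length(p$periods)) median(p$periods) else break_min
  is_break <- gaps > break_min & gaps > 1.25 * med_T
  c(count = sum(is_break),
    degree = min(1, sum(gaps[is_break]) / utterance_duration))
}

## per-utterance phonation base measures (internal work-horse)
phonation_measures <- function(x, fs, f0_min = 75, f0_max = 500,
                               voicing_threshold = 0.45, break_min = 0.016) {
  dur <- length(x) / fs
  if (dur < 3 / f0_min)
    return(NULL)                     # too short for period estimation
  pt <- suppressWarnings(track_pitch(x, f0_min = f0_min, f0_max = f0_max,
                                     voicing_threshold = voicing_threshold,
                                     rate = fs))
  if (!any(pt$voiced)) return(NULL)
  pulses <- extract_pulses(x, pt)
  if (length(pulses$periods) < 2) return(NULL)
  h <- harmonicity(pt)
  vb <- voice_breaks(pulses, dur, break_min)
  c(f0 = mean(pt$f0[pt$voiced]),
    hnr = unname(h["hnr"]), nhr = unname(h["nhr"]),
    shimmer = suppressWarnings(shimmer_local(pulses)),
    jitter = suppressWarnings(jitter_local(pulses)),
    nvb = unname(vb["count"]), dvb = unname(vb["degree"]))
}

#' Phonation and voice-quality feature block
#'
#' Computes the seven base measures (F0, HNR, NHR, shimmer, jitter, number
#' and degree of voice breaks) per utterance and summarizes each by its
#' mean, SD and variance across utterances (population convention), giving
#' 21 features. Utterances too short for period estimation (under 3 periods
#' at `f0_min`) or without voiced material are skipped.
#'
#' @param track a `patient_track`
#' @param f0_min,f0_max pitch range in Hz
#' @param voicing_threshold voicing decision threshold on r
#' @param break_min voice-break gap threshold in seconds
#' @return named numeric vector of 21 features (class `phonation_features`)
#' @export
phonation_features <- function(track, f0_min = 75, f0_max = 500,
                               voicing_threshold = 0.45, break_min = 0.016) {
  stopifnot(inherits(track, "patient_track"))
  per_utt <- lapply(track$utterances, phonation_measures, fs = track$rate,
                    f0_min = f0_min, f0_max = f0_max,
                    voicing_threshold = voicing_threshold,
                    break_min = break_min)
  summarize_phonation(per_utt)
}

summarize_phonation <- function(per_utt) {
  per_utt <- per_utt[!vapply(per_utt, is.null, TRUE)]
  bases <- c("f0", "hnr", "nhr", "shimmer", "jitter", "nvb", "dvb")
  if (length(per_utt) == 0) {
    warning("no utterance was long/voiced enough for phonation analysis")
    m <- matrix(0, 0, length(bases), dimnames = list(NULL, bases))
  } else m <- do.call(rbind, per_utt)
  out <- unlist(lapply(bases, function(b) {
    v <- if (nrow(m)) m[, b] else numeric(0)
    setNames(c(mean0(v), pop_sd(v), pop_var(v)),
             paste0(b, c("_mean", "_std", "_var")))
  }))
  class(out) <- c("phonation_features", class(out))
  out
}
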