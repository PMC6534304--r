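## cached mel filterbank (n_mels x nbins), triangles on the mel scale
.mel_cache <- new.env(parent = emptyenv())
mel_filterbank <- function(fs, nfft, n_mels) {
  key <- paste(fs, nfft, n_mels, sep = "_")
  if (!is.null(.mel_cache[[key]])) return(.mel_cache[[key]])
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(0, mel(fs / 2), length.out = n_mels + 2L))
  bins <- (0:(nfft %/% 2)) * fs / nfft
  fb <- matrix(0, n_mels, length(bins))
  for (j in seq_len(n_mels)) {
    lo <- pts[j]; c0 <- pts[j + 1]; hi <- pts[j + 2]
    up <- bins >= lo & bins <= c0
    dn <- bins > c0 & bins <= hi
    fb[j, up] <- (bins[up] - lo) / max(c0 - lo, 1e-12)
    fb[j, dn] <- (hi - bins[dn]) / max(hi - c0, 1e-12)
  }
  .mel_cache[[key]] <- fb
  fb
}

#' Frame-level spectral analysis (MFCC / log-mel / subband energy shares)
#'
#' Standard MFCC front end: pre-emphasis, 25 ms Hamming-windowed frames at a
#' 10 ms hop, power spectrum, 26 triangular mel filters spanning 0 to the
#' Nyquist frequency. `fbank` is the log filter energy (floored); `mfcc` is
#' the DCT-II of the log energies keeping coefficients c1..c13 (c0, a pure
#' gain term, is excluded); `ssc` is each filter's share of the total filter
#' energy per frame (the normalized-subband-energy variant: all 26 shares sum
#' to exactly 1, of which the first 13 are retained). Silent frames get
#' uniform shares.
#'
#' @param w a [waveform()] or numeric vector
#' @param frame,hop analysis window and hop in seconds
#' @param n_fft FFT length (default: next power of two above the frame)
#' @param n_mels number of mel filters
#' @param n_keep number of MFCC / SSC coefficients retained
#' @param preemphasis pre-emphasis coefficient
#' @param log_floor floor applied to filter energies before the log
#' @param rate sampling rate when `w` is a bare vector
#' @return a `frame_spectra` object: matrices `mfcc` (n_keep x frames),
#'   `fbank` (n_mels x frames), `ssc` (n_keep x frames), `ssc_full`
#'   (n_mels x frames) and `frame_times`
#' @export
frame_spectra <- function(w, frame = 0.025, hop = 0.010, n_fft = NULL,
                          n_mels = 26, n_keep = 13, preemphasis = 0.97,
                          log_floor = 1e-10, rate = NULL) {
  if (inherits(w, "waveform")) { x <- w$samples; fs <- w$rate }
  else { x <- as.numeric(w); fs <- rate %||% 16000 }
  frame_n <- round(frame * fs); hop_n <- round(hop * fs)
  if (length(x) < frame_n)
    stop("waveform shorter than one analysis frame (", frame_n, " samples)")
  n_fft <- n_fft %||% nextn(frame_n, 2)
  y <- c(x[1] * (1 - preemphasis), x[-1] - preemphasis * x[-length(x)])
  starts <- frame_starts(length(y), frame_n, hop_n)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_n - 1)) / (frame_n - 1))
  P <- cpp_power_frames(y, starts, frame_n, win, n_fft)
  E <- mel_filterbank(fs, n_fft, n_mels) %*% P
  fbank <- log(pmax(E, log_floor))
  j <- seq_len(n_mels)
  dct <- sqrt(2 / n_mels) *
    cos(outer(seq_len(n_keep), j - 0.5) * pi / n_mels)
  mfcc <- dct %*% fbank
  tot <- colSums(E)
  ssc_full <- E / rep(pmax(tot, 1e-300), each = n_mels)
  silent <- tot <= n_mels * log_floor
  if (any(silent)) ssc_full[, silent] <- 1 / n_mels
  structure(list(mfcc = mfcc, fbank = fbank,
                 ssc = ssc_full[seq_len(n_keep), , drop = FALSE],
                 ssc_full = ssc_full,
                 frame_times = (starts - 1) / fs + frame_n / fs / 2),
            class = "frame_spectra")
}

#' Averaged weighted spectral coefficients (AWSC)
#'
#' Per utterance and coefficient subgroup, the frame-mean coefficient vector
#' divided by the utterance duration, so slower / more drawn-out deliveries
#' shrink the coefficients (units 1/second). Scaling the duration of a fixed
#' set of frames by k scales the AWSC by 1/k exactly.
#'
#' @param fs_obj a `frame_spectra`
#' @param utterance_duration utterance length in seconds (> 0)
#' @return an `awsc` object: list of vectors `mfcc`, `fbank`, `ssc`
#' @export
awsc <- function(fs_obj, utterance_duration) {
  stopifnot(inherits(fs_obj, "frame_spectra"))
  if (!is.finite(utterance_duration) || utterance_duration <= 0)
    stop("utterance duration must be positive")
  structure(list(mfcc = rowMeans(fs_obj$mfcc) / utterance_duration,
                 fbank = rowMeans(fs_obj$fbank) / utterance_duration,
                 ssc = rowMeans(fs_obj$ssc) / utterance_duration),
            class = "awsc")
}

#' Descriptive spectral feature block
#'
#' Each utterance's AWSC subgroup vector is collapsed to a scalar (mean over
#' its coefficients) and the mean, SD, min, max and variance of those scalars
#' across utterances are reported per subgroup (population convention),
#' giving 15 features. With `scalarize = FALSE` the statistics are taken
#' over the pooled utterance-by-coefficient values instead.
#'
#' @param awsc_list list of `awsc` objects, one per utterance
#' @param scalarize collapse coefficients to a per-utterance scalar first
#' @return named numeric vector of 15 features (class `spectral_features`)
#' @export
spectral_features <- function(awsc_list, scalarize = TRUE) {
  stopifnot(length(awsc_list) >= 1)
  out <- unlist(lapply(c("mfcc", "fbank", "ssc"), function(g) {
    v <- if (scalarize)
      vapply(awsc_list, function(a) mean(a[[g]]), 0)
    else
      unlist(lapply(awsc_list, function(a) a[[g]]))
    setNames(c(mean0(v), pop_sd(v), min(v), max(v), pop_var(v)),
             paste0(g, c("_mean", "_std", "_min", "_max", "_var")))
  }))
  class(out) <- c("spectral_features", class(out))
  out
}
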