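# shared fixtures, all generated in code

FS <- 16000

tone <- function(dur, freq = 210, fs = FS, amp = 0.5) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs)
}

silence <- function(dur, fs = FS) numeric(round(dur * fs))

## a patient track from raw utterance vectors
track_of <- function(..., fs = FS, latencies = NULL) {
  vocemark:::patient_track_from_utterances(list(...), fs,
                                           latencies = latencies)
}

## a pulse_train with explicit periods/amplitudes (one run)
pulse_train_of <- function(periods, amplitudes = NULL) {
  times <- c(0, cumsum(periods))
  structure(list(times = times,
                 amplitudes = amplitudes %||% rep(1, length(times)),
                 run = rep(1L, length(times)),
                 periods = periods,
                 period_run = rep(1L, length(periods))),
            class = "pulse_train")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small-scale generator parameters: same class structure, ~1 minute of talk
tiny_params <- function(talk_fmd = c(1.6, 0.4), talk_nd = c(1.1, 0.3)) {
  p <- vocemark:::cohort_defaults()
  p$talk_total_min <- list(FMD = talk_fmd, ND = talk_nd)
  p
}

tiny_cohort <- function(seed, n_per_class = 3, effect_scale = 1) {
  cohort_spec(n_per_class = n_per_class, seed = seed,
              effect_scale = effect_scale, params = tiny_params())
}

## memoised full-scale cohort evaluations for the acceptance checks; the
## tables are expensive, so every test that needs cohort seed s shares them
.cohort_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    cs <- cohort_spec(n_per_class = 15, seed = seed, effect_scale = 1)
    tabs <- suppressWarnings(cohort_feature_tables(cs))
    r1 <- suppressWarnings(nested_kfold(tabs$recordings, seed = seed))
    r2 <- suppressWarnings(logout_eval(tabs$segments, seed = seed))
    .cohort_cache[[key]] <- list(tabs = tabs, recordings = r1, segments = r2)
  }
  .cohort_cache[[key]]
}

## brute-force Mann-Whitney U: pairwise wins plus half-ties
brute_u <- function(x, y) {
  u1 <- 0
  for (a in x) for (b in y) u1 <- u1 + (a > b) + 0.5 * (a == b)
  min(u1, length(x) * length(y) - u1)
}
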