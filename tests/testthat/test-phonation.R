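test_that("pitch tracking recovers pure-tone frequency and rejects noise", {
  pt <- track_pitch(tone(1, 200), rate = FS)
  expect_true(all(pt$voiced))
  expect_lt(max(abs(pt$f0 - 200)), 1)

  set.seed(1)
  ptn <- track_pitch(rnorm(FS), rate = FS)
  expect_gte(mean(!ptn$voiced), 0.9)

  pts <- track_pitch(silence(1), rate = FS)
  expect_false(any(pts$voiced))
})

test_that("pulse extraction marks one pulse per cycle", {
  v <- voice_spec(f0 = 100, jitter_sigma = 0, shimmer_sigma = 0,
                  target_hnr = Inf)
  sv <- synthesize_voice(v, 1, seed = 3)
  pu <- extract_pulses(sv$waveform, track_pitch(sv$waveform))
  expect_equal(length(pu$times), length(sv$pulses$times), tolerance = 0.03)
  expect_equal(median(pu$periods), 0.010, tolerance = 1e-4)

  x <- tone(0.5, 200)
  pu2 <- extract_pulses(x, track_pitch(x, rate = FS))
  expect_equal(length(pu2$periods), 0.5 * 200 - 1, tolerance = 6)
  expect_equal(median(pu2$periods), 0.005, tolerance = 1e-4)

  pu3 <- extract_pulses(silence(1), track_pitch(silence(1), rate = FS))
  expect_length(pu3$times, 0)
})

test_that("jitter and shimmer follow their defining formulas", {
  expect_equal(jitter_local(pulse_train_of(rep(0.01, 50))), 0)
  p <- pulse_train_of(rep(c(0.010, 0.0102), 25))
  expect_equal(jitter_local(p), 100 * 0.0002 / 0.0101, tolerance = 1e-6)

  a <- pulse_train_of(rep(0.005, 40), amplitudes = rep(c(1, 0.9), length.out = 41))
  expect_equal(shimmer_local(a), 100 * 0.1 / mean(rep(c(1, 0.9),
                                                      length.out = 41)),
               tolerance = 0.1)
  expect_equal(shimmer_local(pulse_train_of(rep(0.005, 40))), 0)

  expect_warning(j0 <- jitter_local(pulse_train_of(numeric(0))), "period")
  expect_equal(j0, 0)
})

test_that("synthetic perturbations are recovered quantitatively", {
  v <- voice_spec(f0 = 201.3, jitter_sigma = 0.01, shimmer_sigma = 0,
                  target_hnr = Inf)
  sv <- synthesize_voice(v, 3, seed = 6)
  pu <- extract_pulses(sv$waveform, track_pitch(sv$waveform))
  pred <- 200 * 0.01 / sqrt(pi)       # E|dT|/T for iid N(0, sigma T0)
  expect_gt(jitter_local(pu), 0.8)
  expect_lt(jitter_local(pu), 1.6)
  expect_equal(jitter_local(pu), pred, tolerance = 0.35)

  vs <- voice_spec(f0 = 201.3, jitter_sigma = 0, shimmer_sigma = 0.05,
                   target_hnr = Inf)
  svs <- synthesize_voice(vs, 3, seed = 7)
  pus <- extract_pulses(svs$waveform, track_pitch(svs$waveform))
  expect_equal(shimmer_local(pus), 200 * 0.05 / sqrt(pi), tolerance = 0.2)
})

test_that("harmonicity obeys the frame-level identity and SNR construction", {
  pt <- structure(data.frame(t = 1:3, f0 = c(200, 200, 200),
                             r = c(0.5, 0.9, 0.99),
                             voiced = c(TRUE, TRUE, TRUE)),
                  class = c("pitch_track", "data.frame"))
  h <- harmonicity(pt)
  r <- c(0.5, 0.9, 0.99)
  expect_equal(unname(h["hnr"]), mean(10 * log10(r / (1 - r))))
  expect_equal(unname(h["nhr"]), mean((1 - r) / r))
  # single frame at r = 0.5 sits exactly at 0 dB / ratio 1
  pt1 <- structure(data.frame(t = 1, f0 = 200, r = 0.5, voiced = TRUE),
                   class = c("pitch_track", "data.frame"))
  expect_equal(unname(harmonicity(pt1)), c(0, 1), tolerance = 1e-12)
  # frame-wise identity nhr == 10^(-hnr/10) by algebra
  hnr_f <- 10 * log10(r / (1 - r))
  expect_equal((1 - r) / r, 10^(-hnr_f / 10), tolerance = 1e-12)

  x <- tone(1, 210, amp = 0.4)
  expect_gte(unname(harmonicity(track_pitch(x, rate = FS))["hnr"]), 25)
  set.seed(11)
  sn <- x + rnorm(length(x), 0, sqrt(mean(x^2) / 10))
  expect_equal(unname(harmonicity(track_pitch(sn, rate = FS))["hnr"]), 10,
               tolerance = 3)
})

test_that("HNR decreases monotonically as noise is added", {
  x <- tone(1, 210, amp = 0.4)
  set.seed(12)
  hnrs <- vapply(c(30, 20, 10, 5, 0), function(snr) {
    y <- x + rnorm(length(x), 0, sqrt(mean(x^2) / 10^(snr / 10)))
    unname(harmonicity(track_pitch(y, rate = FS))["hnr"])
  }, 0)
  expect_true(all(diff(hnrs) < 0))
})

test_that("voice breaks count qualifying inter-pulse gaps", {
  # 100 Hz train with one 20 ms gap
  per <- rep(0.010, 60)
  times <- cumsum(c(0, per))
  times[31:61] <- times[31:61] + 0.010        # turns one gap into 20 ms
  p <- structure(list(times = times, amplitudes = rep(1, 61),
                      run = rep(1L, 61), periods = diff(times),
                      period_run = rep(1L, 60)), class = "pulse_train")
  vb <- voice_breaks(p, utterance_duration = 1)
  expect_equal(unname(vb["count"]), 1)

  expect_equal(unname(voice_breaks(pulse_train_of(rep(0.01, 50)), 1)),
               c(0, 0))

  # three inserted gaps of 0.1, 0.2, 0.3 s over 10 s
  per2 <- rep(0.010, 400)
  t2 <- cumsum(c(0, per2))
  # widen three inter-pulse gaps to exactly 0.1, 0.2, 0.3 s
  t2[101:401] <- t2[101:401] + 0.1 - 0.01
  t2[201:401] <- t2[201:401] + 0.2 - 0.01
  t2[301:401] <- t2[301:401] + 0.3 - 0.01
  p2 <- structure(list(times = t2, amplitudes = rep(1, 401),
                       run = rep(1L, 401), periods = diff(t2),
                       period_run = rep(1L, 400)), class = "pulse_train")
  vb2 <- voice_breaks(p2, utterance_duration = 10)
  expect_equal(unname(vb2["count"]), 3)
  expect_equal(unname(vb2["degree"]), 0.06, tolerance = 1e-6)
  expect_gte(unname(vb2["degree"]), 0)
  expect_lte(unname(vb2["degree"]), 1)
})

test_that("inserted voice breaks are recovered from audio", {
  v <- voice_spec(f0 = 200, jitter_sigma = 0.005, shimmer_sigma = 0.02,
                  target_hnr = 25, break_rate = 0.3)
  sv <- synthesize_voice(v, 10, seed = 9)
  pu <- extract_pulses(sv$waveform, track_pitch(sv$waveform))
  vb <- voice_breaks(pu, 10)
  expect_equal(unname(vb["count"]), nrow(sv$breaks), tolerance = 1)
})

test_that("jitter and shimmer are invariant to gain and time shift", {
  v <- voice_spec(f0 = 197, jitter_sigma = 0.01, shimmer_sigma = 0.03,
                  target_hnr = Inf)
  sv <- synthesize_voice(v, 2, seed = 5)
  x <- sv$waveform$samples
  m <- function(x) {
    pu <- extract_pulses(x, track_pitch(x, rate = FS))
    c(jitter_local(pu), shimmer_local(pu))
  }
  base <- m(x)
  expect_equal(m(3 * x), base, tolerance = 1e-6)
  expect_equal(m(c(silence(0.25), x)), base, tolerance = 0.15)
})

test_that("phonation summary uses population statistics across utterances", {
  per_utt <- list(c(f0 = 180, hnr = 10, nhr = 0.1, shimmer = 5, jitter = 1,
                    nvb = 0, dvb = 0),
                  c(f0 = 220, hnr = 12, nhr = 0.08, shimmer = 6, jitter = 2,
                    nvb = 2, dvb = 0.1))
  s <- vocemark:::summarize_phonation(per_utt)
  expect_length(s, 21)
  expect_equal(unname(s["f0_mean"]), 200)
  expect_equal(unname(s["f0_std"]), 20)
  expect_equal(unname(s["f0_var"]), 400)
  expect_equal(unname(s["dvb_var"]), unname(s["dvb_std"])^2,
               tolerance = 1e-12)
  # a single utterance yields zero dispersion
  s1 <- vocemark:::summarize_phonation(per_utt[1])
  expect_equal(unname(s1["f0_std"]), 0)
  expect_equal(unname(s1["f0_var"]), 0)
})
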