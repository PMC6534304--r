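test_that("16-bit PCM WAV writing and reading round-trips bit-exactly", {
  f1 <- tempfile(fileext = ".wav"); f2 <- tempfile(fileext = ".wav")
  x <- round(runif(12345, -1, 1) * 32767) / 32768
  write_wav(x, FS, f1)
  w <- read_wav(f1)
  expect_equal(w$rate, FS)
  expect_identical(w$samples, x)
  write_wav(w$samples, w$rate, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("load_audio canonicalizes rate and channels", {
  f <- tempfile(fileext = ".wav")
  # 2 s stereo at 44.1 kHz -> 32000 mono samples at 16 kHz
  st <- cbind(tone(2, 500, fs = 44100), tone(2, 500, fs = 44100))
  write_wav(st, 44100, f)
  w <- load_audio(f, 16000)
  expect_equal(w$rate, 16000)
  expect_length(w$samples, 32000)
  # constant-zero second stays 16000 zeros
  write_wav(numeric(16000), 16000, f)
  expect_equal(load_audio(f)$samples, numeric(16000))
  # native-rate mono passes through up to quantization
  x <- tone(0.5)
  write_wav(x, 16000, f)
  expect_equal(load_audio(f)$samples, x, tolerance = 1e-4)
  expect_error(load_audio(tempfile()), "WAV")
})

test_that("downsampling preserves the dominant spectral peak of a band-limited signal", {
  f <- tempfile(fileext = ".wav")
  write_wav(tone(1, 1000, fs = 44100), 44100, f)
  w <- load_audio(f, 16000)
  sp <- Mod(fft(w$samples))[1:8000]
  peak_hz <- (which.max(sp) - 1) * 16000 / length(w$samples)
  expect_lt(abs(peak_hz - 1000), 16000 / length(w$samples) + 1e-9)
})

test_that("TSV turn annotations parse with and without a header", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("0.0\t3.0\tdoctor", "3.8\t10.0\tpatient"), f)
  ann <- read_turns(f)
  expect_s3_class(ann, "turn_annotation")
  expect_equal(ann$speaker, c("doctor", "patient"))
  writeLines(c("start\tend\tspeaker", "0\t2\tpatient"), f)
  expect_equal(nrow(read_turns(f)), 1)
  expect_error(turn_annotation(data.frame(start = 2, end = 1,
                                          speaker = "patient")), "start")
  expect_error(turn_annotation(data.frame(start = c(0, 1), end = c(2, 3),
                                          speaker = c("a", "b"))),
               "overlap")
})

test_that("TextGrid interval tiers are read as turn annotations", {
  f <- tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 10", "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:", '        class = "IntervalTier"',
    '        name = "speaker"', "        xmin = 0", "        xmax = 10",
    "        intervals: size = 3",
    "        intervals [1]:", "            xmin = 0",
    "            xmax = 3", '            text = "doctor"',
    "        intervals [2]:", "            xmin = 3",
    "            xmax = 3.8", '            text = ""',
    "        intervals [3]:", "            xmin = 3.8",
    "            xmax = 10", '            text = "patient"'), f)
  ann <- read_textgrid(f)
  expect_equal(nrow(ann), 2)            # the empty interval is dropped
  expect_equal(ann$speaker, c("doctor", "patient"))
  expect_equal(ann$start, c(0, 3.8))
})

test_that("patient-track isolation computes latencies and totals", {
  w <- waveform(c(tone(3, 120), silence(0.8), tone(6.2)), FS)
  ann <- turn_annotation(data.frame(
    start = c(0, 3.8), end = c(3, 10),
    speaker = c("doctor", "patient")))
  tr <- extract_patient_track(w, ann)
  expect_length(tr$utterances, 1)
  expect_equal(length(tr$utterances[[1]]) / FS, 6.2, tolerance = 1e-4)
  expect_equal(tr$total_turn_time, 6.2, tolerance = 1e-6)
  expect_equal(tr$response_latencies, 0.8, tolerance = 1e-9)

  # patient-first turn has no latency entry
  ann2 <- turn_annotation(data.frame(
    start = c(0, 4), end = c(3, 6), speaker = c("patient", "doctor")))
  tr2 <- extract_patient_track(waveform(silence(6), FS), ann2)
  expect_true(is.na(tr2$response_latencies[1]))

  # three 2 s patient turns -> total 6 s
  ann3 <- turn_annotation(data.frame(
    start = c(0, 2, 4, 6, 8, 10),
    end = c(2, 4, 6, 8, 10, 12),
    speaker = rep(c("patient", "doctor"), 3)))
  tr3 <- extract_patient_track(waveform(silence(12), FS), ann3)
  expect_equal(tr3$total_turn_time, 6)

  expect_error(extract_patient_track(
    waveform(silence(5), FS),
    turn_annotation(data.frame(start = 0, end = 6, speaker = "patient"))),
    "beyond")
  expect_error(extract_patient_track(
    waveform(silence(5), FS),
    turn_annotation(data.frame(start = 0, end = 2, speaker = "doctor"))),
    "patient")
})

test_that("spectral noise gate attenuates noise and preserves the tone band", {
  set.seed(42)
  sig <- tone(3, 200, amp = 0.4)
  noise <- rnorm(length(sig), 0, 0.01)
  w <- waveform(sig + noise, FS)
  prof <- waveform(rnorm(FS / 2, 0, 0.01), FS)
  out <- spectral_noise_gate(w, prof, reduction_db = 24)
  expect_length(out$samples, length(w$samples))
  band_power <- function(x, lo, hi) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(sp) - 1) * FS / length(sp)
    sum(sp[f >= lo & f <= hi])
  }
  tone_in <- band_power(w$samples, 150, 250)
  tone_out <- band_power(out$samples, 150, 250)
  expect_lt(abs(10 * log10(tone_out / tone_in)), 1)
  noise_in <- band_power(w$samples, 2000, 7000)
  noise_out <- band_power(out$samples, 2000, 7000)
  expect_gte(10 * log10(noise_in / noise_out), 12)

  # silence in, silence out
  ws <- waveform(silence(1), FS)
  expect_lt(max(abs(spectral_noise_gate(ws, prof)$samples)), 1e-8)

  # zero reduction leaves the signal untouched
  out0 <- spectral_noise_gate(w, prof, reduction_db = 0)
  expect_equal(out0$samples, w$samples, tolerance = 1e-9)

  expect_error(spectral_noise_gate(w, waveform(rnorm(1000), FS)), "frame")
  expect_error(spectral_noise_gate(w, waveform(rnorm(3000), FS)), "0.25")
})
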