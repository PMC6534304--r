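test_that("the noiseless periodic limit has no measurable perturbation", {
  v <- voice_spec(f0 = 201.3, jitter_sigma = 0, shimmer_sigma = 0,
                  target_hnr = Inf, break_rate = 0)
  sv <- synthesize_voice(v, 2, seed = 5)
  pu <- extract_pulses(sv$waveform, track_pitch(sv$waveform))
  expect_lt(jitter_local(pu), 0.2)
  expect_lt(shimmer_local(pu), 0.2)
  expect_equal(unname(voice_breaks(pu, 2)["count"]), 0)
  # true pulse instants are recovered one-for-one
  expect_equal(length(pu$times), length(sv$pulses$times))
})

test_that("the synthesizer hits its target harmonicity", {
  v <- voice_spec(f0 = 201.3, jitter_sigma = 0.005, shimmer_sigma = 0.02,
                  target_hnr = 10)
  sv <- synthesize_voice(v, 2, seed = 8)
  h <- harmonicity(track_pitch(sv$waveform))
  expect_equal(unname(h["hnr"]), 10, tolerance = 3)
})

test_that("inserted breaks appear in the ground truth and the audio", {
  v <- voice_spec(f0 = 200, jitter_sigma = 0.005, shimmer_sigma = 0.02,
                  target_hnr = 25, break_rate = 0.3)
  sv <- synthesize_voice(v, 10, seed = 9)
  expect_equal(nrow(sv$breaks), 3, tolerance = 2)
  gaps <- diff(sv$pulses$times)
  expect_equal(sum(gaps > 0.016 & gaps > 1.25 * median(gaps)),
               nrow(sv$breaks))
  expect_error(synthesize_voice(
    voice_spec(f0 = 200, break_rate = 40, break_duration = c(0.4, 0.5)),
    1, seed = 1), "infeasible")
})

test_that("dialogue synthesis is reproducible and meets its talk budget", {
  d <- dialogue_spec("ND", patient_talk_total = 1.2)
  v <- voice_spec(f0 = 196, break_rate = 0.4, target_hnr = 18)
  a <- synthesize_dialogue(d, v, seed = 11)
  b <- synthesize_dialogue(d, v, seed = 11)
  expect_identical(a$waveform$samples, b$waveform$samples)
  expect_identical(a$truth, b$truth)
  expect_gte(a$truth$patient_talk_s, 1.2 * 60)
  expect_lte(a$truth$patient_talk_s, 1.2 * 60 * 1.1 + 10)
  # annotation covers both speakers, patient turns non-empty
  expect_setequal(unique(a$annotation$speaker), c("doctor", "patient"))
})

test_that("a zero-pause dialogue yields zero detected pauses", {
  d <- dialogue_spec("FMD", within_turn_pause_rate = 0,
                     patient_talk_total = 0.7)
  v <- voice_spec(f0 = 205, break_rate = 0, target_hnr = 25)
  dl <- synthesize_dialogue(d, v, seed = 12)
  expect_equal(nrow(dl$truth$pauses), 0)
  tr <- extract_patient_track(dl$waveform, dl$annotation)
  seg <- suppressWarnings(detect_segments(tr))
  expect_equal(nrow(seg$pauses), 0)
})

test_that("generated pauses are recovered from the audio (interval F1)", {
  d <- dialogue_spec("ND", patient_talk_total = 2,
                     within_turn_pause_rate = 0.25)
  v <- voice_spec(f0 = 195.7, break_rate = 0.4, target_hnr = 18)
  dl <- synthesize_dialogue(d, v, seed = 11)
  tr <- extract_patient_track(dl$waveform, dl$annotation)
  seg <- detect_segments(tr)
  # map truth pauses (global time) onto the patient-material timeline
  tt <- tr$turn_times
  off <- c(0, cumsum(tt[, 2] - tt[, 1]))
  to_pat <- function(s) { i <- findInterval(s, tt[, 1]); off[i] + s - tt[i, 1] }
  truth <- cbind(to_pat(dl$truth$pauses$start), to_pat(dl$truth$pauses$end))
  hits <- 0
  for (i in seq_len(nrow(truth)))
    hits <- hits + any(abs(seg$pauses[, 1] - truth[i, 1]) < 0.05 &
                         abs(seg$pauses[, 2] - truth[i, 2]) < 0.05)
  f1 <- 2 * hits / (nrow(truth) + nrow(seg$pauses))
  expect_gte(f1, 0.95)
})

test_that("response latencies in the truth log match the annotation gaps", {
  d <- dialogue_spec("FMD", patient_talk_total = 1)
  v <- voice_spec(f0 = 210)
  dl <- synthesize_dialogue(d, v, seed = 13)
  tr <- extract_patient_track(dl$waveform, dl$annotation)
  lat <- tr$response_latencies
  expect_equal(lat[is.finite(lat)], dl$truth$latencies, tolerance = 1e-3)
})

test_that("cohort generation on disk is byte-reproducible", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  cs <- tiny_cohort(77, n_per_class = 1)
  m1 <- generate_cohort(cs, d1)
  m2 <- generate_cohort(cs, d2)
  expect_equal(nrow(m1), 2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$wav[i], "raw", file.size(m1$wav[i])),
                     readBin(m2$wav[i], "raw", file.size(m2$wav[i])))
    expect_identical(readLines(m1$truth[i]), readLines(m2$truth[i]))
    expect_identical(readLines(m1$annotation[i]), readLines(m2$annotation[i]))
  }
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("classes are exchangeable at effect scale zero", {
  set.seed(19)
  pvals <- c()
  for (s in 1:6) {
    cs <- cohort_spec(n_per_class = 6, seed = 1000 + s, effect_scale = 0,
                      params = tiny_params())
    roster <- vocemark:::cohort_roster(cs)
    qty <- t(vapply(seq_len(nrow(roster)), function(i) {
      sp <- vocemark:::with_seed(roster$seed[i],
        vocemark:::draw_patient_specs(cs, roster$label[i]))
      c(talk = sp$dialogue$patient_talk_total,
        prate = sp$dialogue$within_turn_pause_rate,
        pdur = sp$dialogue$pause_duration_dist[1],
        lat = sp$dialogue$response_latency_dist[1],
        brk = sp$voice$break_rate)
    }, numeric(5)))
    cl <- roster$label
    pvals <- c(pvals, apply(qty, 2, function(v)
      suppressWarnings(wilcox.test(v[cl == "FMD"], v[cl == "ND"])$p.value)))
  }
  expect_gte(mean(pvals >= 0.05), 0.85)
})

test_that("classification accuracy does not decrease with effect scale", {
  accs <- vapply(c(0, 1), function(es) {
    out <- vapply(1:2, function(s) {
      cs <- cohort_spec(n_per_class = 6, seed = 400 + s, effect_scale = es,
                        params = tiny_params())
      tabs <- suppressWarnings(
        cohort_feature_tables(cs, scenarios = "recordings"))
      r <- suppressWarnings(
        nested_kfold(tabs$recordings, k = 3, route = "utest",
                     classifiers = "svm_linear", n_feat_grid = c(5, 20),
                     inner_k = 3, seed = s, regimes = "selected"))
      r$results$mean_accuracy
    }, 0)
    mean(out)
  }, 0)
  expect_gte(accs[2] + 0.05, accs[1])
})
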