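---
title: "Acoustic voice markers for memory-clinic conversations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic voice markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Memory clinics see two broad groups of patients with memory complaints:
those with progressive neurodegenerative disorders (ND: Alzheimer's disease,
amnestic MCI, behavioural-variant FTD, vascular dementia) and those with
functional memory disorder (FMD), whose complaints are not associated with
objective decline. The two groups talk differently during history taking:
ND patients tend to contribute less, with more and longer pauses, longer
response latencies, shorter utterances and more voice breaks. `vocemark`
implements an acoustics-only screening pipeline over such conversations:

1. **Patient isolation** — a mono 16 kHz recording plus a speaker-turn
   annotation (TSV or Praat TextGrid) is reduced to the patient's turns;
   turn-start latencies are the gaps after the preceding non-patient turn.
2. **Feature extraction** — each recording (or each one-minute window of
   patient material) is summarized by 51 features in three blocks:
   speech/silence timing (15), phonation/voice quality (21), and
   duration-weighted spectral descriptors (15).
3. **Feature selection** — SVM recursive feature elimination (RFE),
   random-forest embedded importances, or Mann-Whitney U ranking.
4. **Evaluation** — five classifier families under two leakage-controlled
   schemes: nested stratified 5-fold cross-validation over recordings, and
   leave-one-group-out (LOGOUT) over one-minute segments, where all segments
   of one speaker are held out together.

Because clinical recordings of this kind cannot be shared, the package
carries a source-filter synthetic-cohort generator whose ground truth makes
every stage testable end to end.

## The feature set

**Speech/silence block (15).** Energy-based voice activity detection runs
per patient turn: RMS intensity in non-overlapping 10 ms frames, in dB; a
frame is silent when it falls more than 25 dB below the turn's
95th-percentile intensity (a peak-relative threshold, so the block is
invariant to recording gain). The 10 ms boxcar grid was chosen over longer
overlapping windows because a 25 ms window overhangs speech onsets/offsets
by more than one hop at this threshold, while the boxcar grid bounds every
boundary error by a single hop by construction. Runs of silence of at least 0.25 s are pauses
and runs of voicing of at least 0.5 s are speech segments; shorter runs
merge into their surroundings. The features are the mean response time, the
max/mean/SD of pause and speech durations, duration ratios against the
patient's total turn time, the pause rate, and the mean/SD/variance of
"long" speech segments (>= 0.8 s, which excludes filler-like
vocalisations). Sixteen named candidates exist; the canonical 15 drop
`ratio_max_speech_total` (configurable via `voc_config(segmental_drop=)`),
reconciling the block's stated size with the named ratio list.

**Phonation block (21).** An autocorrelation pitch tracker (40 ms frames,
10 ms hop, search range 75-500 Hz) estimates the period per frame. The lag
search runs on a low-passed, 4x decimated copy; candidate lags are
parabolically interpolated local maxima compared under a 0.05/octave
penalty, and the winner is re-evaluated at the full rate with an explicit
octave-down check. This two-resolution design exists because a non-integer
period quantizes differently at the fundamental lag and its multiples, so
raw grid correlations cannot be compared across octaves. Voicing requires
r >= 0.45 (the conventional default). Glottal pulses are marked one per
period at waveform maxima, refined to sub-sample precision; periods between
consecutive pulses are re-estimated by waveform matching, which suppresses
the timing noise that formant ringing puts on raw peak positions. From the
pulse train: local jitter and shimmer (mean consecutive-cycle perturbation
over the mean, in percent; cycles outside [0.7, 1.4] x the median period are
excluded as tracking glitches), HNR/NHR from the voicing strength
(10 log10(r/(1-r)) per frame, so nhr = 10^(-hnr/10) exactly), and voice
breaks (inter-pulse gaps > 16 ms that also exceed 1.25 x the median period —
the bare 16 ms rule would count ordinary cycles below 62.5 Hz). Each of the
seven base measures is summarized by mean, SD and variance across
utterances, using the population convention throughout.

**Spectral block (15).** A standard MFCC front end (pre-emphasis 0.97,
25 ms Hamming frames, 10 ms hop, 26 triangular mel filters to the Nyquist
frequency, log floor 1e-10) produces per frame: 26 log filter energies
(Fbank), their DCT-II coefficients c1..c13 (MFCC; c0 is excluded as a pure
gain term), and 13 subband energy shares (SSC — each filter's share of the
total filter energy; the shares over all 26 filters sum to exactly 1).
Frame means per utterance are divided by the utterance duration, giving
averaged weighted spectral coefficients (AWSC, units 1/s): slower,
more drawn-out speech shrinks the coefficients, injecting the timing
contrast into the spectral block by design. Each subgroup's AWSC vector is
collapsed to a scalar (mean over coefficients; `scalarize = FALSE` pools the
utterance-by-coefficient matrix instead) and summarized across utterances by
mean, SD, min, max and variance. Note that MFCC and SSC are gain-invariant
but plain log filter energies are not — a property of the standard
definition, kept as such.

## Selection and evaluation design

Standardization is the standard score (x - mu) / sigma with the training
rows' mean and *population* SD, fitted strictly inside training data;
zero-variance columns pass through centred with a warning.

The three selection routes rank all 51 features: RFE drops the feature with
the smallest absolute linear-SVM weight one at a time (ties drop the later
column; two features per step on tables over 100 rows, where the fit chain
would otherwise dominate runtime); the embedded route uses impurity
importances of a fixed-seed random forest; the statistical route sorts by
ascending Mann-Whitney U (reported as min(U1, U2), the SPSS convention)
with tie-corrected p-values from `wilcox.test`. The RFE evaluator uses
cost = 0.01: at 24-row training folds with 51 standardized features, heavier
regularization makes the weight vector — and therefore the elimination
order — dramatically more stable (measured as the fraction of genuinely
informative features in the top 9 across resampled folds).

Both validation schemes fit the ranking once per outer split on the outer
training rows; the inner folds then tune the retained feature count
(9, 22 or 51) and the classifier's hyper-parameters against that ranking in
a two-stage search (count first at the middle grid point, then the grid at
the chosen count). Nothing from an outer test fold ever reaches the
standardizer, the ranking or the tuning. The deliberately broken
`leak_selection = TRUE` mode ranks on the full table and exists only so the
test suite can demonstrate the optimistic bias it causes on pure-noise data.

Classifier families and grids: linear SVM (cost 0.01-10), random forest
(100/300 trees, unlimited or depth-5), AdaBoost with decision stumps
(SAMME, 50/200 rounds; the stump search is vectorised over all features via
cumulative sums in presorted order), a single-hidden-layer MLP (16 or 64
tanh units, trained full-batch with Adam, 150 epochs, L2 1e-4 — the usual
quasi-Newton fitters scale quadratically in the weight count and are far
too slow at hidden size 64), and a hinge-loss linear model trained by
Pegasos-style SGD with tail averaging (alpha 1e-4/1e-3). All fits are
deterministic under the run seed.

LOGOUT uses one outer split per speaker (30 for the default cohort) and
group-aware inner folds with k = 3, keeping about ten speakers per inner
fold; accuracy is reported segment-pooled (primary) and as the per-speaker
mean (secondary), since the two differ when group sizes differ. The nested
recording-level scheme uses inner k = 5.

## What the synthetic cohort emulates

`cohort_spec()` draws, per patient, a dialogue specification and a voice
specification, and synthesizes an alternating doctor-patient conversation:
glottal pulse trains with per-cycle period and amplitude perturbation are
placed with windowed-sinc sub-sample precision, shaped by /a/-like formant
resonators (700/1220/2600 Hz), mixed with white noise to a target HNR, and
interrupted by silent voice breaks; the doctor speaks at a disjoint F0
(110 Hz). Ground-truth logs record every utterance, pause, latency, pulse
and break, so every downstream measurement can be checked against what was
generated.

The class-conditional defaults are the study conditions:

* **Talk time** — FMD 11.5 ± 6.3 min vs ND 6.2 ± 4.5 min (the clinical talk-time
  contrast the cohort emulates), truncated below at 1 min. One-minute windowing of a
  15 + 15 cohort therefore yields a few hundred segments at roughly a
  60/40 FMD/ND split. (The clinically reported segment count of 230 is actually
  inconsistent with those same talk-time means, which imply ~265 in
  expectation; the generator follows the talk times.)
* **Timing contrasts** — ND patients pause more often (0.24 vs 0.10
  pauses/s) and longer (0.75 vs 0.48 s), answer more slowly (1.5 vs 0.7 s),
  speak in shorter utterances (2.3 vs 3.2 s), and show more voice breaks
  (0.55 vs 0.15 /s) with mildly lower HNR (18 vs 19 dB). Magnitudes were
  calibrated once so that the synthetic task reproduces the clinical
  study's observed difficulty: the strongest single features reach effect
  sizes around d = 2-2.5 (the level implied by the reported top rank
  statistics at n = 15 + 15), all-features scenario-1 accuracy lands near
  90%, and feature selection yields a positive average gain.
* **Class-neutral structure** — pitch is a female/male mixture
  (57% female; 200 ± 20 vs 125 ± 15 Hz), jitter and shimmer are identical
  across classes (the clinical study found pitch and perturbation measures
  non-significant), each recording carries its own ambient noise floor
  (speech-to-ambient 38 ± 3 dB) and a first-order microphone/room tilt
  (sd 0.15), and conversational behaviour drifts within a session (AR(1)
  on the log scale, correlation ~0.9/turn, sd 0.5 for hesitancy and 0.35
  for verbosity). These nuisance factors make the phonation-pitch and
  spectral blocks noisy across recordings — which is what gives feature
  selection its advantage — and the within-session drift makes one-minute
  segments genuinely weaker samples than whole recordings, as observed
  clinically.
* **`effect_scale`** interpolates every class contrast towards the pooled
  midpoint; 0 gives exchangeable classes (a null cohort), used by the
  leakage and calibration checks.

What the generator does **not** emulate: language content (utterances are
vowel-like), filled pauses as lexical items (the short-segment rule stands
in for them), companion speakers, channel artifacts beyond tilt + stationary
noise, and any correlation between pause behaviour and voice quality within
class (parameters are drawn independently; the clinical covariance is
unknown). Passing tests therefore demonstrate that the measurement and
validation machinery is correct and leak-free under realistic statistical
structure — not that the classifier accuracies transfer to real clinical
audio.

## Numerical choices and degenerate inputs

* Resampling is polyphase (`signal::resample`); WAV I/O is 16-bit PCM and
  round-trips bit-exactly.
* The spectral noise gate uses 2048-point Hann frames at 50% overlap with
  exact overlap-add reconstruction; magnitudes and the noise mean + 1.5 SD
  threshold are band-averaged over 9 bins before comparison, and gains are
  smoothed over 3 frames. Raw short-time magnitudes are heavy-tailed — a
  per-bin comparison leaves the tail ungated and caps the achievable
  attenuation near 8 dB, while the band-averaged decision delivers the
  nominal reduction. `reduction_db = 0` returns the input to numerical
  tolerance. Off by default for synthetic input.
* Empty statistics never produce NaN: degenerate denominators (no pauses,
  no voiced frames, fewer than two periods) yield 0 with a warning so the
  feature matrix stays complete.
* Utterances shorter than 3 periods at `f0_min` are skipped for phonation;
  silent frames get uniform subband shares.
* Between-turn gaps are response latencies, never pauses; pauses are
  within-turn only. Overlapping-turn gaps clamp to zero.
* All randomness flows from one seed; per-recording and per-fold substreams
  are derived with a Lehmer step, and stochastic fitters receive explicit
  seeds, so identical (config, seed) reproduce byte-identical outputs.

## Problem sizes in the checks

The packaged checks run the full clinical scale — 15 + 15 recordings per
cohort with Table-2-scale talk times (~4-5 hours of audio per cohort) —
with three cohort replicates at fixed seeds for the end-to-end accuracy
pattern, which keeps the complete suite within a practical runtime on one
CPU; the remaining properties (perturbation recovery, interval exactness,
rank-statistic oracles, leakage canary, split integrity) use purpose-built
small constructions. The acceptance script (`scripts/acceptance.R`)
likewise evaluates three fresh cohorts derived from its `--seed`.

## Known limitations

* The r-based HNR saturates near 35-40 dB and is compressed on strongly
  jittered voices (cycle misalignment reads as noise) — matching the
  behaviour, though not necessarily the exact values, of conventional
  voice-report tools.
* RFE rankings at n = 24 remain noisy even with the regularized evaluator;
  the embedded and U-test routes are steadier on small cohorts.
* The 16 ms voice-break rule is period-guarded, so breaks are undefined for
  speakers below ~62 Hz.
* Scenario-2 windows slice turns at exact 60 s boundaries of patient
  material; a turn fragment shorter than one pitch frame at a window edge
  is skipped by the phonation block.
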