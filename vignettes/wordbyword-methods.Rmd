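---
title: "Methods: simulating and analysing dyadic word-by-word interactions"
author: "wordbyword package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dyadic word-by-word interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental paradigm

Two participants jointly read aloud sentences, alternating word by word. A
trial consists of 13 words in two sentences; word 4 is a homonym (a word
with two meanings, e.g. German *Flügel* = piano / wing), and word 8 — the
critical word (CW) — disambiguates it. Before each trial every participant
silently reads a prime that fixes one homonym meaning *for them alone*, so
the same CW can be expected for one member of the dyad and unexpected for
the other. Word presentation is driven by an online voice-key: as soon as a
speaker's word offset is detected (at 100 ms resolution), the next word
appears on the partner's screen.

The package provides every stage needed to analyse such a session — and,
because no public recordings exist for this paradigm, a synthetic session
generator with complete ground truth against which every stage is tested.

## Trial-plan generation

`design_spec()` encodes the joint constraints: an even number of trials
(240 by default), 25% incongruent per participant, starters balanced, and
each participant's incongruent trials split 2:1 between trials where they
*perceive* the CW (40) and trials where they *speak* it (20). Because word
8 is even, the trial's starter is always the perceiver of the CW; a trial
is incongruent for at most one participant. These counts reproduce the
published per-sequence ratios: for the words a participant speaks after
perceiving the CW (CW+1, CW+3, CW+5) the expected:unexpected ratio is
80:40, and for the sequence containing the spoken CW (CW, CW+2, CW+4) it
is 100:20. `build_trial_plan()` performs a seeded assignment that satisfies
the counts exactly or fails with the violated constraint named;
`validate_plan()` re-derives every invariant from scratch.

Since the full stimulus list is not public, `sentence_lexicon()` carries
the two published example items (the *Flügel* and *Bank* sentences with
their primes) and generates pseudo-word placeholder items of matched
syntactic frame and letter-count profile, flagged by a `synth_` id prefix.
Semantic plausibility of placeholders is out of scope — downstream stages
only consume letter counts and labels.

## The synthetic dyadic session

`synth_session()` emulates the three recorded streams with a common clock:

* **Audio** (44.1 kHz, one channel per participant). Each word is a
  harmonic voiced burst (f0 drawn from 110–180 Hz, decaying formant-shaped
  harmonics) under a raised-cosine attack (10 ms), amplitude-modulated
  sustain and raised-cosine decay (30 ms). Word duration is lognormal with
  median `0.30 s + 0.045 s x letters` and sigma 0.12, calibrated so the
  grand-average word duration is about 0.54 s with SD near 0.07 s. The
  *true* onset/offset of a word are the first/last crossings of 10% of its
  envelope peak; the coarse voice-key markers are these times rounded up
  to the 100 ms grid, exactly as an amplitude-threshold voice-key would
  lag-quantize them.
* **Reaction times.** The interval from a word's visual presentation to
  its speech onset is gamma distributed with an inverse-link linear
  predictor: intercept 2.04 (mean 0.49 s), a slower first word
  (link shift −0.5), a word-length slope, random participant intercepts
  (SD 0.08) and, for words 8–13, the speaker's congruency effect (+0.022
  on the link scale, i.e. slightly *faster* after unexpected words,
  matching the direction reported for this paradigm). Shape 30 gives a
  realistic ~18% coefficient of variation.
* **EEG** (500 Hz, the 26-electrode cap: 24 signal channels, reference
  FCz, ground AFz). Background noise is 1/f^2-shaped, built from eight
  smooth common spatial sources plus a channel-specific part (so channels
  are spatially correlated, as on a real scalp), plus amplitude-modulated
  10 Hz alpha with occipital topography. Event-related components are
  Gaussian kernels time-locked to the *partner's* true speech onsets:
  N100 (peak 114 ms, SD 20 ms, −2 µV, frontocentral), P200 (250 ms,
  35 ms, +3 µV, central), N400 (480 ms, 50 ms, −4 µV, centroparietal) and
  P600 (600 ms, 55 ms, +2.5 µV, parietal). Heard *incongruent* CWs
  receive additive deltas (+2, −3, +2 µV on P200/N400/P600); the first
  heard word of each trial doubles the N100 (the auditory onset response
  to the first speech after silence). Optional single-trial latency
  jitter scales one latent draw per event by each component's jitter SD,
  so jittered components of an event shift coherently — the natural model
  of trial-level processing-speed variability.
* **Artifacts and transport.** Blinks (Poisson, 200 µV frontal bumps),
  jaw EMG during own speech on the temporal channels, lip-smack clicks
  50–200 ms before word onsets, and Bluetooth packet loss (sample
  deletion with real-time timestamps preserved). The first 20 s of a
  session are artifact-free and serve as burst-cleaning calibration.

**Calibration note.** Background noise amplitude (bandlimited SD 1.5 µV,
alpha 1 µV) was fixed once so that planted effects of a few microvolts are
recoverable from roughly 40 trials per condition — the trial count the
design actually yields per participant and condition. Real EEG is noisier;
what passing tests show is that the *pipeline* is correct and calibrated,
not that effect recovery at these trial counts is guaranteed for real
recordings. Component topographies are near-zero at the mastoids, which is
the physiological premise of mastoid re-referencing; topography spread is
0.6 sphere-chord units.

## Offline speech-event refinement

The voice-key's 100 ms quantization is far too coarse for ERP analysis, so
onsets are re-estimated from the audio. For each coarse marker the channel
is epoched (−0.5 to +1 s), highpass filtered at 35 Hz (erasing
low-frequency fluctuations), and downsampled to 1470 Hz. Three feature
traces are computed: an amplitude envelope (moving average, filter length
300 samples), the first two mel-cepstral coefficient traces (frame 128,
hop 16, 16 mel filters, interpolated to the 1470 Hz base), and a sliding
RMS (window 32). Abrupt RMS changes are located by exact penalized
change-in-mean segmentation (a PELT-style dynamic program; the penalty
defaults to `5 * var(trace) * log(n)`, which yields one to three
candidates on clean words). A candidate is accepted only if, within a
30 ms validation window, the envelope rises by at least 20% of its epoch
peak *and* at least one cepstral trace shifts by 0.25 SD — this is the
guard that rejects lip smacks and other clicks, which excite the RMS but
not a sustained envelope/voicing change. The accepted changepoint is then
snapped to the nearest 10%-of-peak crossing of a lightly smoothed
envelope, mirroring the ground-truth onset definition, which removes the
segmentation's systematic mid-ramp bias. Offsets run the identical
procedure on the time-reversed epoch. If no candidate passes, the coarse
marker is kept and flagged `coarse_fallback`.

The printed 730 Hz and 600 Hz smoothing cutoffs sit at or beyond the
735 Hz Nyquist of the downsampled trace; they are clamped to 0.95 x
Nyquist (near-pass-through smoothers) while the configuration retains the
nominal values.

## Stream repair

Wireless transmission can drop samples. Gaps are detected from per-sample
timestamps: any delta exceeding 1.5 nominal periods is a gap of
`round(delta * rate) - 1` lost samples. Markers (which live on the session
clock) are mapped to the nearest-timestamp sample, so events after a gap
land on the correct sample despite the shortened stream; markers inside a
gap are flagged and mapped to the first post-gap sample. Lost samples are
*not* interpolated — epochs overlapping a gap are dropped with a logged
reason, which is conservative and testable.

## ERP preprocessing

`preprocess_eeg()` chains: zero-phase Hann-windowed FIR band-pass 0.1–30 Hz
(−6 dB at the cutoffs; 16501 taps so the 0.1 Hz edge is honoured; applied
once with group-delay compensation), bad-channel flagging (flat variance
or best-neighbour correlation below 0.25), a simplified burst cleaner,
re-referencing to averaged mastoids (TP9/TP10), order-4 spherical-spline
interpolation of the flagged channels (Perrin-style g-series, 20 terms,
ridge 1e-5), packet-loss-aware marker alignment, and epoching (−500 to
+1500 ms, half-open windows, baseline −100 to 0 ms, ms-to-sample rounding
half away from zero).

The burst cleaner is an explicitly simplified analogue of artifact
subspace reconstruction: principal directions are learned from the
calibration segment; in half-overlapping 0.5 s windows, components whose
RMS exceeds `cutoff_k = 8` times their calibration RMS are projected out
and the window is cross-faded back, leaving non-deviant samples untouched.
Parity with the reference implementation is a non-goal; the contract
(windows deviant in component space are reconstructed from the calibration
subspace) is what is tested.

Epoch rejection removes epochs whose peak absolute amplitude exceeds the
pool mean + 3 SD, applied once over the heard-word pool (a per-condition
variant is available via subsetting first). The rejection statistic is not
dictated by the procedure's description; peak amplitude was chosen for
simplicity and testability, with mean global field power as a config
alternative. Conditions are compared at matched trial counts: the larger
condition is randomly subsampled (seeded) to the smaller one.

## Latency-corrected ERP reconstruction

Word-by-word interaction has high inter-trial latency variability, which
smears conventional averages. `ride_decompose()` separates each
condition's epochs into a stimulus-locked component S (0–250 ms, the
N100) and two cognitive components with free single-trial latencies, C1
(150–350 ms, the P200) and C2 (300–700 ms, the N400), without a response
cluster (the paradigm requires no overt manual response). Estimation
alternates: given waveforms, each trial's component latency is the lag
maximizing the channel-summed cross-correlation between the trial residual
and the component, on the 2 ms sample grid within half the component
window, ties broken toward the smaller absolute lag (the raw
cross-correlation is smoothed over 9 lags before peak-picking, because
band-limited noise makes the raw peak wander); given latencies, each
component is the cosine-tapered median across trials of the residual
after aligning by its latencies. Latencies are median-centred every
iteration. During iteration the locked component is windowed like the
others, so it cannot absorb the smeared average of a jittered component;
after convergence the locked component is re-estimated over the full epoch
as the stimulus-locked residue. Consequently the reconstruction — the sum
of all components at median (zero) latency — equals the plain trial
average *exactly* when all latencies are zero, and restores smeared
amplitudes when they are not. Convergence: waveform RMS change below
0.02 µV or 20 iterations (then the result is returned flagged
`converged = FALSE` with a warning, never an error).

## Component statistics

Mean amplitudes are taken over the printed windows — P200 166–336 ms, N400
350–500 ms, P600 500–650 ms, N100 effect 60–160 ms — on the midline
electrodes (Fz, Cz, CPz, Pz) or on the four lateral quadrants, each
averaged per subject before analysis. `rm_anova()` implements the one- and
two-factor fully within-subject ANOVA from the textbook sum-of-squares
decomposition; for every effect with more than one numerator df Mauchly's
test (Box/Anderson chi-square series) is run on the effect's contrast
covariance and, when it signals a violation at alpha = .05 (the procedure
states the rule but not the threshold; .05 is the conventional choice),
the Greenhouse-Geisser-corrected p-value is reported with the original
degrees of freedom alongside. Effect sizes are partial eta squared. The
implementation is oracle-tested against `stats::anova.mlm` /
`stats::mauchly.test` and against from-definition sums of squares. The
N100 attenuation analysis (word 1 vs words 2–4 on the midline, 60–160 ms)
delegates to the same routine.

## Reaction-time analysis

RT = visual presentation to own speech onset, per spoken word. Exclusions:
RTs below 300 ms or above 1000 ms (strict inequalities — boundary values
are kept) and words whose preceding spoken word's refined offset postdates
the visual presentation (speech overlap). Analysis splits the
post-critical words into the two consecutive spoken sequences and fits,
per sequence, a gamma GLMM with the inverse link via `lme4::glmer`: fixed
congruency (effects-coded) and word position (ordered three-level factor),
random intercepts for participant and for word length (one level per
integer letter count — the stated, unusual structure is followed
literally; word length proxies item variability, and item itself is
confounded with congruency). Coefficients are reported on the link scale
with back-transformed predicted means per condition. Fixed effects are
assessed by likelihood-ratio tests against the model without the effect;
the reported df is the actual parameter-count difference (for the
three-level ordered position factor that is 2, and the package reports
what it computes rather than echoing any other convention).

## Problem sizes and numerical choices

The shipped tests exercise reduced but fully structured study conditions,
chosen as the smallest sizes at which each statistical property is
meaningfully testable: 6–18 trial sessions for signal-level round trips,
60-trial audio sessions for onset-detection accuracy (median error and
false-early rate over 780 words), a 120-trial dyad (40 matched trials per
congruency condition after pooling the two listeners) for delta recovery,
108 single-condition epochs for latency-jitter recovery, 500 replicates
for the ANOVA type-I calibration and 200 four-dyad replicates for the
GLMM likelihood-ratio null calibration; the full 240-trial / 13-dyad
design remains available throughout and is used for the trial-plan and
GLMM-fit outputs of the acceptance script. Seeds for every stage derive
from one master seed by a fixed counter scheme (`derive_seed()`), so any
stage can be re-run in isolation.

## Known limitations

* The synthetic speech is not phonetically realistic (no coarticulation —
  which the paradigm itself prevents — no consonant structure); onset
  detection accuracy on real speech, where onsets can be fricative or
  plosive, will be worse than on these voiced bursts.
* The burst cleaner is a simplified stand-in for artifact subspace
  reconstruction and is tested against its own contract only.
* The latency decomposition is a documented simplified variant of
  residue-iteration decomposition (median-based robust averaging plus
  windowed cross-correlation latencies); parity with the reference
  toolbox is a non-goal.
* Group-level statistics on a single dyad are degenerate by construction;
  multi-dyad simulation is provided for the RT models
  (`synth_rt_study()`), while multi-dyad ERP group analysis is left to
  the user's study design.
* Baseline-free analysis of the CW effects is available by passing
  `baseline = NULL` to the epoching, but no acceptance number is attached
  to that comparison.
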