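---
title: "Methods: from raw turning-session LFP to band-power statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw turning-session LFP to band-power statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpturn)
```

## The problem

Intracranial microstimulation of a midbrain motor nucleus evokes turning
in birds, and the local field potential (LFP) around free and evoked
turns carries state-dependent oscillations in five avian frequency bands
(A 0.5–3, B 4–12, C 13–60, D 61–130, E 131–200 Hz). Quantifying those
oscillations requires three things that this package provides as tested,
composable steps: removal of stimulation artifacts that are an order of
magnitude larger than the signal, standard signal conditioning, and a
within-subject factorial analysis of log band power.

Because raw recordings of this kind are rarely shareable, the package
treats the synthetic-data generator as a first-class module: it encodes
the statistical structure the analysis assumes, so every downstream
stage can be validated against known ground truth.

## Synthetic sessions

`generate_session()` builds a continuous 4-channel session (left/right
recording electrodes paired with left/right stimulation-site
electrodes). Each trial block spans a 2 s pre window, the behavioural
interval, and a 2 s post window; blocks are separated by resting
background. Within a block every channel receives an independent
realisation of the state's background model:

* five band-limited Gaussian components, synthesised by FFT-domain
  masking of white noise and rescaled to the state's configured RMS gain
  per band (the masking gives exact band confinement; gains are exact by
  construction and verified by an independent Welch filter-bank oracle);
* pink (1/f) noise restricted to the 0.05–500 Hz acquisition band,
  12 µV RMS by default;
* a 10 µV, 50 Hz mains sinusoid with random phase per segment;
* a 2 µV/s linear drift.

The default per-state band gains were chosen once so that the *mean
power density* ordering across bands reproduces the qualitative state
profile of midbrain turning recordings — B-band dominance at rest and
under 40 Hz stimulation, a C-band boost under 60 Hz stimulation, and
elevated C/D/E power with D maximal during active and 80 Hz evoked
turning. Density matters: the bands differ in width, and the 1/f
background loads the slow bands, so gains are larger in the high bands
than a naive amplitude reading would suggest. The absolute resting scale
(≈20 µV RMS total) is a modelling choice — typical reports give resting
LFPs of tens of microvolts and artifacts "of several hundred", and the
analysis is scale-free — and it is exposed in `synth_config()`.

Active-turn durations are drawn from a normal distribution with mean
1.961 s and SD 0.201 s, truncated below at 0.5 s. Stimulation trials
superpose a biphasic cathodic-leading pulse train (40/60/80 Hz, 1 ms
pulses, 2 s) whose spike amplitude is `artifact_spike_ratio` (default
12, constrained > 10) times the channel's resting peak, scaled by an
ipsi/contralateral coupling factor, followed by a deterministic
exponential tail (80 µV, τ = 5 ms) that is identical across pulses in
continuous time. Pulse edges use a 1 ns guard on the half-open pulse
interval so that sample-grid coincidences do not flip a sample in or out
of the pulse.

The default inter-trial interval is 4 s. The behavioural protocol this
emulates used 2-minute gaps; the gaps carry no analysed signal, so the
compressed profile changes nothing downstream, and `iti_s = 120`
restores full fidelity. Awake-immobile "trials" are represented by a
`TRIAL_START` anchor with the during window following it — a convention
of this package, since event-locked structure for rest periods is not
standardised.

What the generator does **not** emulate: biophysical neural dynamics,
volume conduction between electrodes, behaviourally locked transients
(movement onset potentials), non-stationarity within a state, or
electrode drift/impedance changes. Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it assumes, not
that it is robust to every pathology of real recordings.

## Artifact suppression

The algorithm follows the classical template-subtraction/blanking
family:

1. **Detection.** Within `[STIM_ON − 50 ms, STIM_OFF + 50 ms]`, samples
   of the stimulation-site channel exceeding `threshold_k` robust SDs
   (1.4826 × MAD) of the 2 s pre-stimulation baseline are clustered;
   crossings within 2 ms of a cluster's first crossing join it. The
   default `threshold_k = 8` sits well above background excursions and
   well below the >10× artifact spikes. The artifact time is the
   midpoint of the cluster's first and last crossing: anchoring at the
   first crossing would leave the trailing part of a 1 ms biphasic pulse
   outside the fixed 1.4 ms excision window whenever the pulse spans
   four samples at 3 kHz, so the midpoint is used and the window then
   covers every cluster geometry the pulse can produce. Detection times
   from the stimulation-site channel are shared with its paired
   recording channels (the artifact is simultaneous across the pair).
2. **Tail templates.** The window `[t + 0.8 ms, t + 0.8 ms + w)` with
   `w = min(20 ms, period − 1.4 ms)` after each spike is collected, and
   tails are averaged pointwise into a template — per channel, per
   stimulation frequency, and per stimulated site. The per-site split
   matters: artifact coupling differs between ipsi- and contralateral
   electrodes, so pooling sides would subtract a mixture template and
   leave a systematic residual. The stimulated site is identified per
   trial as the stimulation channel with the largest artifact amplitude.
   At least `min_tails = 10` tails are required.
3. **Subtraction and excision.** The template is subtracted at each tail
   window (this is the template's purpose; `subtract_tail = FALSE`
   preserves a blanking-only variant), then the 1.4 ms spike window
   (0.6 ms before to 0.8 ms after the artifact time) is excised and
   filled with verbatim copies of the flanking raw signal
   (`[t − 1.2, −0.6)` fills the left half, `[t + 0.8, +1.6)` the right).
   Copies, not interpolation: the replacement keeps the amplitude and
   spectral character of the neighbouring background, and residual seam
   discontinuities are attenuated by the later 1–200 Hz band-pass. When
   a flank would overlap a neighbouring excision window, the nearest
   clean segment of equal length is used instead (reported).

Analytically the excised fraction is `stim_freq × 1.4 ms`: 5.6% at
40 Hz, 8.4% at 60 Hz — both under the 9% working bound for missing
data — and 11.2% at 80 Hz, which necessarily exceeds that bound with a
fixed 1.4 ms window; the fraction is reported per trial rather than
constrained at 80 Hz. On synthetic ground truth the default
configuration achieves perfect detection recall/precision and
cleaned-vs-clean correlations above 0.95 during stimulation; a second
pass finds nothing and is a bit-exact no-op.

## Preprocessing

Order: artifact rejection (at the native rate — sub-millisecond spikes
cannot be represented at 512 Hz) → resample to 512 Hz → 1–200 Hz
band-pass → linear detrend → 50 Hz notch → stimulation-frequency combs →
bipolar re-reference → channel rejection.

* **Resampling** is polyphase rational resampling (3000 → 512 Hz is
  64/375) with a Kaiser-windowed linear-phase FIR (passband to 205 Hz,
  stopband at the lowest aliasing frequency, 70 dB). Each polyphase
  branch is normalised to unit sum, so DC is preserved to machine
  precision. The packaged `signal::resample()` was not used because it
  shows a gain error (a constant input returns 1.127).
* **Filters.** The band-pass is a Butterworth design of order 4 per
  edge applied with `filtfilt` (zero phase, squared magnitude); notches
  are RBJ biquads with Q = 30. Filter families and orders are not
  dictated by the protocol, so they are expressed as testable contracts:
  <5% passband loss at 10 Hz, ≥20 dB at 0.1 and 250 Hz, ≥30 dB at
  notch/comb centres, zero cross-correlation lag. Comb filters notch the
  stimulation frequency and every harmonic below 200 Hz.
* **Re-referencing** subtracts each recording channel's paired
  stimulation-site channel samplewise (`paired_stim_channel` metadata,
  chosen by implantation location/depth).
* **Channel rejection** drops a channel iff its SD pooled over
  during-stimulation windows strictly exceeds 5× the SD pooled over the
  2 s pre-stimulation windows; a ratio of exactly 5 is retained. SDs are
  pooled across trials because the rule yields a single per-channel
  decision.

## Spectral estimation

`welch_psd()` averages Hamming-windowed modified periodograms of
`fs`-sample segments (1.0 Hz resolution) at 50% overlap with density
scaling, so the one-sided PSD integrates to the signal variance
(verified to 10% by Parseval-type tests). Per-segment detrending is
disabled because the chain detrends globally. Band power is the
arithmetic mean of PSD bins with `lo ≤ f ≤ hi` (inclusive). With integer
band edges and 1 Hz bins the gaps between bands (3–4, 12–13, 60–61,
130–131 Hz) contain bins that belong to no band; they are excluded
rather than assigned, and a 60 Hz bin counts toward band C.

Cell values are formed by averaging *linear* band power across a cell's
during epochs and channels and applying `log10` to the cell mean —
the per-subject mean spectra are computed first, then log-transformed.
Base 10 is the convention in the PSD literature; the base is a monotone
rescaling and does not change any F statistic. Whether pre/post epochs
enter the statistics is a config choice (`phase`, default `during`).

`morlet_tfa()` convolves with analytic complex Morlet wavelets
(ω₀ = 6), returning squared magnitude per frequency (1–200 Hz) and
sample; samples within three temporal SDs of an edge are flagged as
edge-contaminated.

## Statistics

`rm_anova3()` implements the balanced fully-within three-factor
decomposition directly: every effect's sum of squares comes from
inclusion–exclusion over marginal means, and every effect is tested
against its own subject-by-effect interaction, df = Π(levels−1) and
(n−1)·Π(levels−1). The implementation is verified to 1e−8 against an
independently coded brute-force decomposition and against
`stats::aov()` `Error()` strata. Published tables for designs of this
shape sometimes print error df that imply a pooled term (e.g. (1, 22)
for a 2-level factor with 12 subjects where (1, 11) is the
subject-by-effect df); this package always uses the standard
within-subject error df.

Sphericity is assessed per effect with Mauchly's chi-square
approximation on the orthonormal contrast scores; the
Greenhouse–Geisser ε = (Σλ)²/(d Σλ²) multiplies both df when Mauchly
rejects at α = 0.05 (conditional policy, the common reading of
"correction applied for failure to meet sphericity"); `always_gg = TRUE`
gives the unconditional variant. Both p values are always reported. When
an error SS is zero the F is reported as NaN with a zero-variance flag
rather than fabricating a value. Under pure-noise simulation the
uncorrected per-effect type-I error is verified to lie in
[0.035, 0.065], and the GG-corrected rejection rate never exceeds the
uncorrected one under induced non-sphericity.

Simple effects (`simple_effects()`) run the one-way RM-ANOVA of one
factor inside each level of another, each slice with its own error term
and ε — matching the small error df such analyses print — rather than a
pooled error (a pooled variant would be a one-line change; the sliced
term is the default because it is robust to slice-specific variance).
`lsd_posthoc()` computes Fisher LSD pairwise t tests on the factor's
marginal means using the factor's RM error term,
t = (mᵢ − mⱼ)/√(2·MSE/n); LSD applies no multiplicity adjustment by
definition. Assumption checks are Shapiro–Wilk per design cell across
subjects (delegating to Royston's algorithm in base R) and classic
mean-centred Levene across the cell groups; Levene grouping across
subjects per cell is this package's reading, as trial-level grouping is
not available at the table stage.

## Numerical conventions and degenerate inputs

* Time is seconds from recording start; sample index = `floor(t·fs)`;
  all windows are half-open `[start, end)`, so abutting epochs are
  disjoint and a 2 s epoch is exactly `2·fs` samples. The during-turn
  window is `[TB, TB + 2 s)` regardless of the actual turn end — the
  protocol extracts fixed 2 s segments, and the mean turn (1.961 s)
  essentially fills it.
* Artifact sample anchoring rounds half-up (`floor(x·fs + 0.5)`) so a
  cluster midpoint falling exactly between samples is placed
  deterministically and the 4-sample excision window always covers the
  spike.
* EDF storage is 16-bit with a symmetric physical range per channel;
  round trips are exact to one quantization step. Physical ranges are
  re-parsed from their 8-character ASCII header representation before
  scaling, so writer and reader agree bit-for-bit. Exact sample counts
  and channel roles travel in a JSON sidecar.
* Degenerate inputs error loudly: empty baselines, too few artifact
  tails, incomplete ANOVA designs (missing cells are named), constant
  samples for Shapiro–Wilk, all channels rejected.

## Problem sizes

The shipped tests validate at desk scale, chosen to keep the default
suite in minutes on one CPU: sessions of 1–10 trials per state with
compressed 2–4 s gaps, 4 subjects × 20 replicates for end-to-end
parameter recovery, 1000 replicates for the ANOVA null calibration at
n = 12 subjects, and 100 trials for the behavioural-duration check.
Statistical conclusions (type-I calibration, recovery rates) inherit the
Monte-Carlo error of those sizes.

## Known limitations

* The artifact model is sampled from a continuous-time deterministic
  tail; real tails vary with electrode polarisation and can drift
  within a session, which template averaging only partially absorbs.
* The fill-in step replaces 5.6–11.2% of stimulated samples with nearby
  background; band power during stimulation is accordingly biased
  toward the background spectrum by that fraction.
* `rm_anova3()` requires a complete balanced design; missing cells must
  be handled upstream (drop the subject or impute) — mixed-model
  alternatives are out of scope.
* The EDF writer targets the package's own reader (and standard
  readers); EDF+ annotations are not supported, events travel as TSV.
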