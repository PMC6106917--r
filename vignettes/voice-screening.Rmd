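---
title: "Methods: acoustic measurement and rule-based voice screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic measurement and rule-based voice screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxscreen)
```

## The problem and the model

A sustained vowel /a/ of about five seconds is the standard stimulus for
objective voice assessment. Under the source–filter view of phonation, the
recorded waveform is a quasi-periodic train of glottal excitations
(the *source*), coloured by vocal-tract resonances (*formants*), plus
aperiodic noise from turbulent airflow at an incompletely closed glottis.
Four numbers summarise the source's health:

* **F0** (Hz) — the vibration rate of the vocal folds;
* **jitter** (%) — mean absolute difference of consecutive periods over the
  mean period, times 100;
* **shimmer** (dB) — mean absolute `20·log10` ratio of consecutive
  peak-to-peak amplitudes;
* **HNR** (dB) — the ratio of periodic to aperiodic signal energy.

The screen compares each value against a fixed healthy range — F0 inside
[189, 280] Hz (female) or [104, 158] Hz (male), bounds inclusive; jitter
strictly below 1.04 %; shimmer strictly below 0.35 dB; HNR strictly above
20 dB — and flags the voice as pathological when any parameter (default
rule) or a majority of them (alternative rule) falls outside. The
endpoint conventions are read directly off how the ranges are printed
(closed interval for F0, strict inequalities for the thresholds) and are
verified in the test suite against every published verdict cell available
to us. No diagnosis is attempted: the output is healthy/pathological, per
parameter and overall.

All analysis happens at a fixed 8 kHz sampling rate; other rates are
polyphase-resampled on input.

## F0 estimation

`estimate_pitch_track()` is a Yin-family estimator: per 40 ms frame the
difference function of the signal against its lagged copy is computed (via
FFT correlation), normalised to the cumulative-mean-normalised difference
function (CMNDF), and the first lag whose CMNDF dips below an absolute
threshold is taken, refined to sub-sample precision by parabolic
interpolation. Three implementation choices matter and were validated
against the synthetic oracle described below:

* **Tracking pre-filter** (`lp_cutoff`, default 1000 Hz, zero-phase).
  Period perturbation misaligns high harmonics roughly in proportion to
  frequency, so on the broadband signal a heavily jittered but perfectly
  voiced vowel loses its CMNDF dips, while the fundamental region keeps
  them. Tracking the low band preserves voicing detection for pathological
  voices; broadband noise still fails the threshold (its CMNDF minima sit
  far higher even after filtering).
* **Voicing threshold** (`threshold`, default 0.20). With the pre-filter in
  place, 0.20 separates perturbed vowels (dips well below) from noise
  (minima well above); the classical 0.15 sits below the dip floor of a
  3 %-jitter vowel and would unvoice it.
* **Lag refinement on the raw difference function.** The cumulative
  normalisation has a rising envelope that skews the minimum of wide,
  single-harmonic dips (a pure tone tracked at 2–3 % error); the raw
  difference function's minimum is unbiased, so the parabola is fitted
  there.

`summarize_f0()` reduces the track to one integer Hz value; it defaults to
the mean over voiced frames, but the pipeline (`analyze_voice()`) uses the
median, which is indifferent to the occasional octave-error frame that
heavy perturbation plus noise produces. The search band is demographic:
female 60–600 Hz, male 50–500 Hz, unknown 50–600 Hz — each strictly
containing its gendered healthy range with wide pathological margins, so an
abnormal F0 is measured rather than clamped. Age is accepted in the
metadata but does not move the band by default (no quantitative adjustment
is established).

## Cycle extraction

Jitter and shimmer are defined on per-cycle periods and amplitudes, so
everything rests on placing one mark per glottal cycle. `extract_cycles()`
marks epochs on the **linear-prediction residual** (order 10): inverse
filtering whitens the formants, leaving the excitation as a sharp pulse per
cycle. Marking dominant waveform peaks instead is tempting but wrong — the
previous cycle's formant tail overlaps the next peak and drags it toward
regularity, which systematically *underestimates* jitter (by roughly a
third, on the synthetic oracle). The residual is band-limited-upsampled
eightfold and each peak refined by parabolic interpolation, giving
sub-sample timing; the search window for the next mark is
[period/1.4, period·1.4] around the expected period, and cycles whose
period deviates from the expectation by more than ×1.5/÷1.5 are discarded
as marking errors. For signals whose residual is degenerate (a pure
sinusoid is annihilated by its own predictor) marking falls back to the
waveform.

Amplitudes are peak-to-peak extents, measured robustly: each cycle,
realigned at its fractional mark, is projected onto the mean cycle shape
(matched filter, computed in the whitened domain where the noise is flat),
and the projection coefficient is scaled by the mean cycle's own
peak-to-peak extent. For a clean signal this equals the literal per-cycle
max − min; in noise it averages the error over the whole cycle instead of
sampling it at two extreme points, which is the difference between a
usable and an unusable shimmer at HNR 10 dB (raw extremes contribute about
1 dB of spurious shimmer there; the projection stays within the tolerance
below).

Two guards make the function honest about bad input: unvoiced gaps of up
to one second inside a voiced stretch are bridged (tracker dropouts on a
sustained vowel), and a recording whose consecutive cycles do not resemble
each other (median inter-cycle correlation below 0.5) raises an
insufficient-cycles error instead of returning noise dressed up as
periods.

## HNR estimation

`hnr_db()`'s default method is cepstral comb-liftering: Hann-windowed log
power spectrum of each two-second segment (50 % overlap — the long window
gives the cepstrum the quefrency resolution an 8 kHz vowel needs),
cepstrum, rahmonics at multiples of 1/F0 liftered out (±1 ms), and the
back-transform taken as the noise-floor estimate. The floor's level is
re-calibrated on the between-harmonics bins: exponentiating a liftered log
spectrum underestimates power (the mean of a log is below the log of a
mean — for χ²₂ spectral bins the gap is exactly ln 2 at the median), so
the floor is shifted to match the median between-harmonics residual plus
`10·log10(1/ln 2)`. Harmonic energy is total minus floor energy, floored
at zero; HNR = 10·log10(H/N), with a −10 dB floor value (and a flag) when
no harmonic structure is detectable. F0 itself is refined by maximising
the spectral comb over a ±3 % grid before the windows are placed —
misplacing the twentieth harmonic by a few bins would otherwise corrupt
the split.

Perturbation is HNR's confound: jitter and shimmer smear the harmonic
lines into sidebands that no purely spectral method can tell from noise,
so a spectral HNR of a 3 %-jitter voice reads the perturbation, not the
additive noise. When a cycle track is available (the pipeline passes its
own), the signal is first whitened and then **pitch-normalised**: every
cycle is resampled to the median period and rescaled to a common RMS.
Because the whitened excitation pulse has the same shape in every cycle,
this re-sharpens the comb exactly, while the additive noise stays
broadband — and since harmonic and noise components share the vocal-tract
colouring, inverse filtering leaves their energy ratio intact. One
residual artefact remains: sub-sample alignment error (bounded below by
the timing Cramér–Rao limit) contributes pseudo-noise that grows as f²,
while the whitened true noise is flat. The between-harmonics floor is
therefore decomposed into a flat part and an f²-shaped part (banded
medians, least squares), and only the flat part is reported as noise.

The autocorrelation method (`method = "autocorrelation"`) implements the
normalised-autocorrelation HNR popularised by Praat, with the window's own
autocorrelation divided out, as an independent cross-method check.

## The synthetic oracle

`synthesize_vowel()` renders a quasi-periodic glottal source: one windowed
band-limited impulse per cycle, placed with sub-sample precision, coloured
by three two-pole resonators approximating /a/ (700/130, 1220/70,
2600/160 Hz centre/bandwidth), plus formant-filtered white noise. The
defining property is *exact* ground truth: the drawn period sequence is
affinely rescaled so the jitter equation evaluates to the target exactly;
the drawn log-amplitude steps are rescaled so the shimmer equation hits
its target exactly; the noise gain is solved so the harmonic-to-noise
energy ratio of the two mixed components equals the HNR target. Identical
spec and seed give bit-identical output, and the generator restores the
global RNG state.

`make_cohort()` emulates a screening-study population: healthy members
draw all four targets comfortably inside the gendered healthy ranges
(F0 at least 12 % of the range width inside its bounds, jitter 0.3–0.8 %,
shimmer 0.05–0.25 dB, HNR 24–28 dB — margins chosen so measurement noise
cannot flip a verdict); pathological members push one or two parameters
clearly outside; gender is drawn with a 64.9 % female share, the
composition typical of voice-clinic cohorts. Five-second recordings are
the default, matching the clinical stimulus.

What the generator does **not** emulate: real glottal pulse shapes and
their open-quotient variation, formant drift and intonation, room
acoustics and microphone colouring, and structured pathological phenomena
(subharmonics, diplophonia, voice breaks, tremor). Passing the recovery
grid therefore shows the measurement chain is correct and well-conditioned
on its own model class — it does not certify clinical accuracy on real
voices, which is why published per-parameter accuracies are reproduced
arithmetically (below) rather than re-measured from audio.

## Validation and problem sizes

The test suite exercises, among others:

* brute-force oracle equality for jitter/shimmer (term-by-term equation
  evaluation, 1000 random tracks, 12 significant digits);
* a 54-point recovery grid — F0 {120, 200, 280} Hz × jitter
  {0.5, 1.5, 3.0} % × shimmer {0.2, 0.5, 1.0} dB × HNR {10, 20} dB, one
  five-second recording each — on which the full pipeline must recover F0
  within 2 %, jitter within ±0.3 points, shimmer within ±0.5 dB and HNR
  within ±3 dB;
* reconstruction of the published screening accuracies from their
  sensitivity/specificity pairs and the 150/58 class split, at one-decimal
  precision;
* reproduction of every published per-parameter verdict cell and
  cross-device dispersion cell bundled with the package.

Three printed verdict cells (all female F0 values inside the healthy
range, printed pathological) and two printed dispersion cells
(inconsistent with their own four measurements) are flagged as anomalies
in the bundled tables rather than silently corrected; the tests assert
agreement on everything else and that the anomaly set is exactly these
known cells. The grid sizes above are also what `scripts/acceptance.R`
re-runs; the whole suite completes in about a minute on one CPU.

## Degenerate inputs and tie-breaks

Zero-length or zero-rate signals are rejected at construction. Validation
flags recordings shorter than 5 s (with one sample period of slack),
clipped beyond 1 % of samples at |x| ≥ 0.999, or quieter than an RMS of
10⁻⁴ — all thresholds configurable. White noise is reported unvoiced and
fails cycle extraction explicitly; a pure tone bypasses the degenerate LP
residual via the waveform fallback. Equal maxima in peak searches resolve
to the earliest. Shimmer refuses zero amplitudes (degenerate-amplitude
error) and both perturbation measures refuse fewer than two cycles. An
HNR with no detectable harmonic energy returns the −10 dB floor with a
flag instead of −Inf. Metrics with zero denominators either raise an
error naming the metric or, in batch reports, are printed as undefined.

## Limitations

* The healthy ranges are a convention, not a law; they are configurable
  (`healthy_ranges()`, YAML override) and gendered only for F0.
* Jitter and shimmer depend on the F0/cycle extraction in any
  implementation; numerical parity with other analyzers is out of scope.
* The perturbation-robust HNR path needs a usable cycle track; for
  recordings where extraction fails, the raw spectral estimate applies and
  will read perturbation as noise.
* The screen's aggregation rule ("any abnormal") maximises sensitivity by
  construction and has correspondingly weak specificity on real cohorts;
  the report records which rule produced its verdict.
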