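# voxscreen

Acoustic voice analysis and rule-based dysphonia screening in R.

Dysphonia — a functional or morphological voice disorder — touches roughly
one person in ten at some point, and half of all voice professionals.
Clinical practice screens for it non-invasively with *acoustic analysis* of
a sustained vowel /a/ held for about five seconds: four parameters carry
most of the diagnostic signal, and each has a conventional healthy range.
`voxscreen` is for speech scientists and biomedical engineers who want that
pipeline as ordinary, scriptable R: measure the parameters, apply the
screen, evaluate the screen's performance, and synthesize test material
whose ground truth is known exactly.

## The measurements

Working at a fixed 8 kHz sampling rate, the package estimates, per
recording:

* **Fundamental frequency (F0)** — the vocal-fold vibration rate, from a
  Yin-style estimator (cumulative-mean-normalised difference function,
  absolute voicing threshold, parabolic lag refinement) searched over a
  gender-aware band.
* **Jitter (%)** — cycle-to-cycle period perturbation,

  `J = 100 · [ (1/(N−1)) Σ |Tᵢ − Tᵢ₊₁| ] / [ (1/N) Σ Tᵢ ]`

  over the N extracted glottal periods Tᵢ.
* **Shimmer (dB)** — cycle-to-cycle amplitude perturbation,

  `S = (1/(N−1)) Σ | 20 log₁₀(Aᵢ₊₁ / Aᵢ) |`

  over the extracted peak-to-peak amplitudes Aᵢ.
* **HNR (dB)** — harmonics-to-noise ratio via cepstral comb-liftering (de
  Krom's approach: rahmonics liftered out of the log spectrum; the
  back-transform is the noise floor), with an autocorrelation method as an
  alternative.

Screening is a fixed IF/THEN rule per parameter: a value inside its healthy
range (F0 189–280 Hz for females, 104–158 Hz for males; jitter < 1.04 %;
shimmer < 0.35 dB; HNR > 20 dB) is *healthy*, anything else *pathological*;
one abnormal parameter makes the overall verdict pathological under the
default aggregation.

## A worked example

```r
library(voxscreen)

# a 5 s synthetic vowel with known ground truth: F0 220 Hz, jitter 1.5 %,
# shimmer 0.4 dB, HNR 18 dB
v <- synthesize_vowel(synthesis_spec(f0 = 220, jitter = 1.5,
                                     shimmer = 0.4, hnr = 18, seed = 42))
a <- analyze_voice(v$recording, subject_meta("female"))
a
#> Acoustic voice analysis
#>   recording: 5.00 s at 8000 Hz
#>   F0         220 Hz
#>   jitter   1.531 %
#>   shimmer  0.515 dB
#>   HNR      17.55 dB

screen(a$profile, subject_meta("female"))
#> Rule-based voice screen (female)
#>   f0       220 Hz       healthy
#>   jitter   1.531 %      pathological
#>   shimmer  0.515 dB     pathological
#>   hnr      17.55 dB     pathological
#>   overall: pathological (rule: any_abnormal)
```

The measured values land on the injected ones (F0 exact, jitter within
0.04 points, shimmer within 0.12 dB, HNR within 0.5 dB here), and the
screen reads them against the gendered healthy ranges: jitter 1.531 ≥
1.04 %, shimmer 0.515 ≥ 0.35 dB and HNR 17.55 ≤ 20 dB are each outside
their range, so the voice is flagged pathological — which is what a jitter
of 1.5 % should produce.

Real recordings enter through `load_recording("file.wav")` (PCM and float
WAV, any rate; resampled internally), and batches through `analyze_batch()`
or the command line:

```sh
inst/cli/voxscreen synthesize --n-healthy 5 --n-pathological 5 --seed 1 --out demo/
inst/cli/voxscreen analyze --metadata demo/meta.csv --out profiles.csv demo/*.wav
inst/cli/voxscreen screen  --in profiles.csv --out report.csv
inst/cli/voxscreen evaluate --in report.csv --out metrics.csv
```

`confusion()`, `metrics_from_confusion()`, `repeatability_rate()` and
`device_dispersion()` provide the evaluation statistics (accuracy,
sensitivity and specificity with *pathological* as the positive class;
repeat-recording agreement; cross-device scatter). `study_table()` exposes
the published clinical evaluation tables bundled as CSV.

## Limitations

The screen is a screen, not a diagnosis: it emits healthy/pathological per
parameter and overall, nothing finer. Numerical parity with any specific
commercial analyzer is not a goal — F0-estimation internals differ across
systems and propagate into jitter and shimmer. See the methods vignette
(`vignettes/voice-screening.Rmd`) for the estimation details, parameter
defaults, and what the synthetic validation does and does not establish.
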