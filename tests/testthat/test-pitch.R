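test_that("demographic search bands contain the gendered healthy ranges", {
  f <- default_search_band(subject_meta("female"))
  expect_lt(f$fmin, 189)
  expect_gt(f$fmax, 280)
  m <- default_search_band(subject_meta("male"))
  expect_lt(m$fmin, 104)
  expect_gt(m$fmax, 158)
  u <- default_search_band(subject_meta("unknown"))
  expect_lte(u$fmin, m$fmin)
  expect_gte(u$fmax, f$fmax)
  expect_error(f0_search_band(300, 200), "fmin")
})

test_that("a pure tone and an impulse train are tracked at their period", {
  tr <- estimate_pitch_track(make_tone(220), default_search_band())
  expect_true(all(tr$voiced_flags))
  expect_lt(abs(stats::median(tr$f0_frames) - 220), 1)

  tri <- estimate_pitch_track(make_impulse_train(40), default_search_band())
  expect_lt(abs(summarize_f0(tri) - 200), 1)
})

test_that("white noise is predominantly unvoiced across seeds", {
  for (seed in 0:9) {
    tr <- estimate_pitch_track(make_white_noise(seed), default_search_band())
    expect_gt(mean(!tr$voiced_flags), 0.5)
  }
})

test_that("F0 estimates are invariant to amplitude scaling", {
  rec <- synthesize_vowel(synthesis_spec(f0 = 180, jitter = 1, shimmer = 0.3,
                                         hnr = 15, seed = 2))$recording
  tr1 <- estimate_pitch_track(rec, default_search_band())
  tr2 <- estimate_pitch_track(voice_recording(rec$samples * 0.05, rec$rate),
                              default_search_band())
  expect_equal(tr1$f0_frames, tr2$f0_frames, tolerance = 1e-8)
})

test_that("summarize_f0 rounds and weights frames as documented", {
  fake <- structure(list(f0_frames = rep(220.4, 10),
                         voiced_flags = rep(TRUE, 10)),
                    class = "pitch_track")
  expect_identical(summarize_f0(fake), 220)
  fake$f0_frames <- c(199, 200, 201)
  fake$voiced_flags <- rep(TRUE, 3)
  expect_identical(summarize_f0(fake), 200)
  # weighted mean by frame counts: 210 x 90, 400 x 10 -> 229
  fake$f0_frames <- c(rep(210, 90), rep(400, 10))
  fake$voiced_flags <- rep(TRUE, 100)
  expect_identical(summarize_f0(fake), 229)
  fake$voiced_flags <- rep(FALSE, 100)
  expect_error(summarize_f0(fake), "no voiced frames")
})

test_that("cycle extraction recovers an exact impulse-train period", {
  rec <- make_impulse_train(40, duration = 5)     # 5 ms at 8 kHz
  tr <- estimate_pitch_track(rec, default_search_band())
  cy <- extract_cycles(rec, tr)
  expect_gt(cy$n_cycles, 900)
  expect_true(all(abs(cy$periods - 0.005) <= 0.000125 + 1e-9))
  expect_equal(length(cy$amplitudes), cy$n_cycles)
})

test_that("an alternating period sequence is recovered within one sample", {
  periods <- rep(c(40L, 41L), 300)                # 5.000 / 5.125 ms
  rec <- make_pulse_vowel(periods)
  tr <- estimate_pitch_track(rec, default_search_band())
  cy <- extract_cycles(rec, tr)
  got <- cy$periods * rec$rate
  # compare to the alternating ground truth, allowing for starting phase
  t1 <- rep(c(40, 41), length.out = length(got))
  t2 <- rep(c(41, 40), length.out = length(got))
  target <- if (mean(abs(got - t1)) <= mean(abs(got - t2))) t1 else t2
  expect_lt(max(abs(got - target)), 1)
  # and the alternation survives: consecutive differences near 1 sample
  expect_gt(mean(abs(diff(got))), 0.75)
})

test_that("white noise yields an insufficient-cycles failure", {
  rec <- make_white_noise(3)
  tr <- estimate_pitch_track(rec, default_search_band())
  expect_error(extract_cycles(rec, tr), "insufficient cycles")
})

test_that("unperturbed vowels sit below the 0.3% jitter noise floor and
           inside the no-octave-error band", {
  for (f0 in c(100, 150, 200, 250, 300)) {
    v <- synthesize_vowel(synthesis_spec(f0 = f0, duration = 5, seed = 4))
    tr <- estimate_pitch_track(v$recording, default_search_band())
    est <- summarize_f0(tr)
    expect_lt(abs(est - f0) / f0, 0.02)
    expect_gte(est / f0, 0.75)
    expect_lte(est / f0, 1.5)
    cy <- extract_cycles(v$recording, tr)
    expect_lt(jitter_percent(cy), 0.3)
  }
})
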