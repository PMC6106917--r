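test_that("a 5 s 8 kHz mono tone round-trips through WAV with the right shape", {
  rec <- make_tone(200, duration = 5, rate = 8000)
  p <- tmp_wav(rec$samples, 8000, bits = 16)
  got <- load_recording(p)
  expect_s3_class(got, "voice_recording")
  expect_length(got$samples, 40000)
  expect_equal(got$rate, 8000)
  expect_equal(got$duration, 5)
  # 16-bit quantisation error bound
  expect_lt(max(abs(got$samples - rec$samples)), 1 / 32000)
})

test_that("float WAV round-trips exactly and other rates are preserved", {
  x <- sin(2 * pi * 200 * (0:22049) / 44100) * 0.5
  p <- tmp_wav(x, 44100, bits = 32)
  got <- load_recording(p)
  expect_equal(got$rate, 44100)
  expect_equal(got$samples, x, tolerance = 1e-7)
})

test_that("stereo input is averaged to mono", {
  left <- rep(0.5, 1000)
  right <- rep(-0.1, 1000)
  p <- tmp_wav(cbind(left, right), 8000, bits = 32)
  got <- load_recording(p)
  expect_equal(got$samples, rep(0.2, 1000), tolerance = 1e-6)
})

test_that("unreadable and corrupt files fail loudly", {
  expect_error(load_recording(tempfile(fileext = ".wav")), "no such file")
  empty <- tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(load_recording(empty), "truncated|empty")
  junk <- tempfile(fileext = ".wav")
  writeBin(as.raw(rep(7, 100)), junk)
  expect_error(load_recording(junk), "RIFF")
})

test_that("resampling preserves a tone's frequency and the sample count", {
  rec <- make_tone(200, duration = 5, rate = 44100)
  out <- resample_to_pipeline_rate(rec, 8000)
  expect_equal(out$rate, 8000)
  expect_length(out$samples, 40000)
  spec <- Mod(stats::fft(out$samples))[1:20000]
  peak_hz <- (which.max(spec) - 1) * 8000 / 40000
  expect_lt(abs(peak_hz - 200), 1)

  # identity at the target rate
  rec8 <- make_tone(200, duration = 5, rate = 8000)
  expect_identical(resample_to_pipeline_rate(rec8, 8000), rec8)

  # length check by sample counting for a non-integer rate ratio
  set.seed(1)
  noisy <- voice_recording(stats::rnorm(80000), 16000)
  expect_length(resample_to_pipeline_rate(noisy, 8000)$samples, 40000)

  expect_error(resample_to_pipeline_rate(rec8, -1), "positive")
})

test_that("validation flags short, silent and clipped recordings", {
  ok <- validate_recording(make_tone(200, duration = 5, rate = 8000))
  expect_true(ok$usable)
  expect_length(ok$reasons, 0)

  short <- validate_recording(make_tone(200, duration = 4.2, rate = 8000))
  expect_false(short$usable)
  expect_equal(short$reasons, "too_short")

  silent <- validate_recording(voice_recording(rep(0, 40000), 8000))
  expect_false(silent$usable)
  expect_equal(silent$reasons, "silent")

  clipped <- validate_recording(make_tone(200, duration = 5, amp = 1.6))
  expect_false(clipped$usable)
  expect_true("clipped" %in% clipped$reasons)
})

test_that("validation is a pure function of samples, rate and thresholds", {
  rec <- make_tone(150, duration = 5)
  a <- validate_recording(rec)
  b <- validate_recording(rec)
  expect_identical(a, b)
  # threshold dependence is explicit
  strict <- validate_recording(rec, silence_rms_floor = 10)
  expect_true("silent" %in% strict$reasons)
})

test_that("trim_silence removes padded edges and keeps the voiced middle", {
  core <- make_tone(200, duration = 2)$samples
  padded <- voice_recording(c(rep(0, 8000), core, rep(0, 8000)), 8000)
  trimmed <- trim_silence(padded)
  expect_lt(abs(trimmed$duration - 2), 0.1)
})
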