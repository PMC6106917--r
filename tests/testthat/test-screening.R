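test_that("published verdict examples reproduce under the default ranges", {
  expect_equal(classify_parameter(217, "f0", "female"), "healthy")
  expect_equal(classify_parameter(188, "f0", "male"), "pathological")
  expect_equal(classify_parameter(1.046, "jitter"), "pathological")
  expect_equal(classify_parameter(0.016, "shimmer"), "healthy")
  expect_equal(classify_parameter(24.36, "hnr", "male"), "healthy")
  expect_equal(classify_parameter(24.36, "hnr", "female"), "healthy")
})

test_that("endpoint conventions: F0 inclusive, jitter/shimmer/hnr strict", {
  expect_equal(classify_parameter(189, "f0", "female"), "healthy")
  expect_equal(classify_parameter(280, "f0", "female"), "healthy")
  expect_equal(classify_parameter(104, "f0", "male"), "healthy")
  expect_equal(classify_parameter(158, "f0", "male"), "healthy")
  expect_equal(classify_parameter(1.04, "jitter"), "pathological")
  expect_equal(classify_parameter(1.0399, "jitter"), "healthy")
  expect_equal(classify_parameter(0.35, "shimmer"), "pathological")
  expect_equal(classify_parameter(20, "hnr"), "pathological")
  expect_equal(classify_parameter(20.0001, "hnr"), "healthy")
  expect_error(classify_parameter(1, "loudness"), "unknown parameter")
})

test_that("classify_parameter agrees with direct interval membership on
           random triples", {
  set.seed(11)
  r <- healthy_ranges()
  n <- 10000
  params <- sample(c("f0", "jitter", "shimmer", "hnr"), n, replace = TRUE)
  genders <- sample(c("female", "male"), n, replace = TRUE)
  values <- stats::runif(n, -5, 600)
  for (i in seq_len(n)) {
    direct <- switch(params[i],
      f0 = {
        iv <- if (genders[i] == "female") r$f0_female else r$f0_male
        values[i] >= iv[1] && values[i] <= iv[2]
      },
      jitter = values[i] < r$jitter_max,
      shimmer = values[i] < r$shimmer_max,
      hnr = values[i] > r$hnr_min)
    expect_identical(classify_parameter(values[i], params[i], genders[i], r),
                     if (direct) "healthy" else "pathological")
  }
})

test_that("screen aggregates the four verdicts under both rules", {
  # all four in range
  ok <- screen(acoustic_profile(220, 0.5, 0.1, 25), subject_meta("female"))
  expect_true(all(ok$verdicts == "healthy"))
  expect_equal(ok$overall, "healthy")

  # published repeat-recording row: F0 217, jitter 1.323, shimmer 1.520,
  # HNR 24.36, female
  rep1 <- screen(acoustic_profile(217, 1.323, 1.520, 24.36),
                 subject_meta("female"))
  expect_equal(unname(rep1$verdicts),
               c("healthy", "pathological", "pathological", "healthy"))
  expect_equal(rep1$overall, "pathological")
  expect_equal(rep1$overall_rule, "any_abnormal")

  # a single abnormal parameter separates the two rules
  one_abn <- acoustic_profile(220, 0.5, 0.1, 19.9)
  expect_equal(screen(one_abn, subject_meta("female"))$overall,
               "pathological")
  expect_equal(screen(one_abn, subject_meta("female"),
                      overall_rule = "majority")$overall, "healthy")
})

test_that("VHI banding matches the published cut points and partitions", {
  expect_equal(classify_vhi(0), "none")
  expect_equal(classify_vhi(32), "none")
  expect_equal(classify_vhi(33), "mild")
  expect_equal(classify_vhi(43), "mild")
  expect_equal(classify_vhi(44), "moderate")
  expect_equal(classify_vhi(60), "moderate")
  expect_equal(classify_vhi(61), "severe")
  expect_equal(classify_vhi(180), "severe")
  expect_error(classify_vhi(181), "0, 180")
  # every score maps to exactly one band
  bands <- classify_vhi(0:180)
  expect_false(anyNA(bands))
  expect_equal(sort(unique(bands)), c("mild", "moderate", "none", "severe"))
})

test_that("RSI banding matches the published cut points and partitions", {
  expect_equal(classify_rsi(12), "none")
  expect_equal(classify_rsi(13), "perceived")
  expect_equal(classify_rsi(45), "perceived")
  expect_error(classify_rsi(46), "0, 45")
  expect_false(anyNA(classify_rsi(0:45)))
})

test_that("ranges load from a YAML config with defaults for missing keys", {
  skip_if_not_installed("yaml")
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("jitter_max: 2.0", "f0_female: [150, 300]"), cfg)
  r <- load_healthy_ranges(cfg)
  expect_equal(r$jitter_max, 2.0)
  expect_equal(r$f0_female, c(150, 300))
  expect_equal(r$shimmer_max, 0.35)     # untouched default
  expect_equal(classify_parameter(1.5, "jitter", ranges = r), "healthy")
})
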