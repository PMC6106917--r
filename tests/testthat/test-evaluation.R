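test_that("confusion tallies with pathological as the positive class", {
  truth <- c(rep("pathological", 10), rep("healthy", 5))
  cc <- confusion(truth, truth)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 10L, tn = 5L, fp = 0L, fn = 0L))

  all_path <- confusion(rep("pathological", 5),
                        c(rep("pathological", 3), rep("healthy", 2)))
  expect_equal(unlist(all_path[c("tp", "tn", "fp", "fn")]),
               c(tp = 3L, tn = 0L, fp = 2L, fn = 0L))

  # random case vs a naive counting oracle
  set.seed(5)
  for (rep in 1:10) {
    pred <- sample(c("healthy", "pathological"), 20, replace = TRUE)
    tru <- sample(c("healthy", "pathological"), 20, replace = TRUE)
    cc <- confusion(pred, tru)
    tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (i in 1:20) {
      key <- if (tru[i] == "pathological") {
        if (pred[i] == "pathological") "tp" else "fn"
      } else {
        if (pred[i] == "pathological") "fp" else "tn"
      }
      tally[key] <- tally[key] + 1L
    }
    expect_equal(unlist(cc[names(tally)]), tally)
  }

  expect_error(confusion(c("healthy"), c("healthy", "healthy")), "length")
  expect_error(confusion("sick", "healthy"), "labels")
})

test_that("metrics reproduce the published jitter row and the degenerate cases", {
  m <- metrics_from_confusion(confusion_counts(tp = 144, tn = 7, fp = 51,
                                               fn = 6))
  expect_equal(round(m[["accuracy"]], 1), 72.6)
  expect_equal(round(m[["sensitivity"]], 1), 96.0)
  expect_equal(round(m[["specificity"]], 1), 12.1)

  sym <- metrics_from_confusion(confusion_counts(50, 50, 50, 50))
  expect_true(all(sym == 50))

  deg <- metrics_from_confusion(confusion_counts(tp = 10, tn = 0, fp = 10,
                                                 fn = 0))
  expect_equal(deg[["sensitivity"]], 100)
  expect_equal(deg[["specificity"]], 0)

  expect_error(
    metrics_from_confusion(confusion_counts(tp = 5, tn = 0, fp = 0, fn = 0)),
    "specificity")
  na_ok <- metrics_from_confusion(
    confusion_counts(tp = 5, tn = 0, fp = 0, fn = 0), allow_undefined = TRUE)
  expect_true(is.na(na_ok[["specificity"]]))
})

test_that("confusion_from_rates reconstructs counts with round-half-up", {
  cc <- confusion_from_rates(150, 58, 0.960, 0.121)
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]),
               c(tp = 144L, fn = 6L, tn = 7L, fp = 51L))

  cc2 <- confusion_from_rates(150, 58, 0.533, 0.569)
  expect_equal(unlist(cc2[c("tp", "fn", "tn", "fp")]),
               c(tp = 80L, fn = 70L, tn = 33L, fp = 25L))

  cc3 <- confusion_from_rates(100, 100, 1, 1)
  expect_equal(unlist(cc3[c("tp", "fn", "tn", "fp")]),
               c(tp = 100L, fn = 0L, tn = 100L, fp = 0L))

  expect_error(confusion_from_rates(0, 5, 0.5, 0.5), "positive")
  expect_error(confusion_from_rates(5, 5, 1.5, 0.5), "fractions")
})

test_that("accuracy equals the class-weighted mean of sensitivity and
           specificity, and reconstruction inverts within rounding", {
  set.seed(9)
  for (rep in 1:25) {
    cc <- confusion_counts(tp = sample(0:80, 1), tn = sample(0:80, 1),
                           fp = sample(1:80, 1), fn = sample(1:80, 1))
    m <- metrics_from_confusion(cc)
    p <- cc$tp + cc$fn
    n <- cc$tn + cc$fp
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * p + m[["specificity"]] * n) / (p + n),
                 tolerance = 1e-10)

    m2 <- metrics_from_confusion(
      confusion_from_rates(p, n, m[["sensitivity"]] / 100,
                           m[["specificity"]] / 100))
    expect_lt(abs(m2[["sensitivity"]] - m[["sensitivity"]]) / 100,
              1 / (2 * min(p, n)) + 1e-10)
    expect_lt(abs(m2[["specificity"]] - m[["specificity"]]) / 100,
              1 / (2 * min(p, n)) + 1e-10)
  }
})

test_that("repeatability rate counts discordant verdict pairs", {
  pairs <- cbind(c(rep("healthy", 5), rep("pathological", 5)),
                 c(rep("healthy", 5), rep("healthy", 5)))
  expect_equal(repeatability_rate(pairs), 0.5)
  expect_equal(repeatability_rate(cbind(rep("healthy", 4), rep("healthy", 4))),
               0)
  expect_error(repeatability_rate(pairs[0, , drop = FALSE]), "no verdict")
})

test_that("device dispersion is the sample standard deviation", {
  expect_equal(round(device_dispersion(c(244, 203, 189, 210)), 2), 23.36)
  expect_equal(round(device_dispersion(c(233, 237, 254, 209)), 2), 18.55)
  expect_equal(device_dispersion(c(5, 5, 5, 5)), 0)
  expect_error(device_dispersion(7), "at least 2")

  # two-pass brute-force oracle to 10 significant digits
  set.seed(13)
  for (rep in 1:20) {
    v <- stats::runif(sample(2:50, 1), 0, 100)
    m <- sum(v) / length(v)
    ss <- 0
    for (x in v) ss <- ss + (x - m)^2
    expect_equal(device_dispersion(v), sqrt(ss / (length(v) - 1)),
                 tolerance = 1e-10)
  }
})
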