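#' Acoustic profile of a recording
#'
#' The four parameters the screen evaluates.
#'
#' @param f0 fundamental frequency in Hz (> 0).
#' @param jitter jitter in percent (>= 0).
#' @param shimmer shimmer in dB (>= 0).
#' @param hnr harmonics-to-noise ratio in dB.
#' @return An object of class \code{acoustic_profile}.
#' @export
acoustic_profile <- function(f0, jitter, shimmer, hnr) {
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  if (!is.finite(jitter) || jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  if (!is.finite(shimmer) || shimmer < 0) stop("shimmer must be >= 0", call. = FALSE)
  if (!is.finite(hnr)) stop("hnr must be finite", call. = FALSE)
  structure(list(f0 = f0, jitter = jitter, shimmer = shimmer, hnr = hnr),
            class = "acoustic_profile")
}

#' @export
print.acoustic_profile <- function(x, ...) {
  cat(sprintf(
    "<acoustic_profile: F0 %g Hz, jitter %.3f %%, shimmer %.3f dB, HNR %.2f dB>\n",
    x$f0, x$jitter, x$shimmer, x$hnr))
  invisible(x)
}

#' Healthy ranges for the acoustic parameters
#'
#' The fixed per-parameter healthy intervals the rule-based screen compares
#' against. Defaults: F0 inside [189, 280] Hz for females and [104, 158] Hz
#' for males (bounds inclusive); jitter strictly below 1.04\%; shimmer
#' strictly below 0.35 dB; HNR strictly above 20 dB (jitter, shimmer and
#' HNR thresholds are gender-independent). Any entry can be overridden, and
#' a full set can be loaded from a YAML/CSV config via
#' [load_healthy_ranges()].
#'
#' @param f0_female,f0_male inclusive \code{c(lo, hi)} intervals in Hz.
#' @param jitter_max exclusive upper limit, percent.
#' @param shimmer_max exclusive upper limit, dB.
#' @param hnr_min exclusive lower limit, dB.
#' @return An object of class \code{healthy_ranges}.
#' @export
healthy_ranges <- function(f0_female = c(189, 280), f0_male = c(104, 158),
                           jitter_max = 1.04, shimmer_max = 0.35,
                           hnr_min = 20) {
  structure(list(f0_female = f0_female, f0_male = f0_male,
                 jitter_max = jitter_max, shimmer_max = shimmer_max,
                 hnr_min = hnr_min),
            class = "healthy_ranges")
}

#' Load healthy ranges from a config file
#'
#' Accepts a YAML file with any of the keys \code{f0_female}, \code{f0_male}
#' (two numbers each), \code{jitter_max}, \code{shimmer_max},
#' \code{hnr_min}; unspecified keys keep their defaults.
#'
#' @param path path to a YAML config file.
#' @return A [healthy_ranges()] object.
#' @export
load_healthy_ranges <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to load range configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  base <- healthy_ranges()
  for (key in intersect(names(cfg), names(base))) base[[key]] <- cfg[[key]]
  class(base) <- "healthy_ranges"
  base
}

#' Classify one acoustic parameter against its healthy range
#'
#' The elementary IF/THEN rule: a value inside the (gender-resolved)
#' healthy interval is \code{"healthy"}, anything else is
#' \code{"pathological"}. F0 bounds are inclusive; the jitter and shimmer
#' limits are strict "<" and the HNR limit strict ">", so a jitter of
#' exactly 1.04\% is pathological.
#'
#' @param value the measured value.
#' @param parameter one of \code{"f0"}, \code{"jitter"}, \code{"shimmer"},
#'   \code{"hnr"}.
#' @param gender \code{"female"} or \code{"male"}; only consulted for F0.
#' @param ranges a [healthy_ranges()] object.
#' @return \code{"healthy"} or \code{"pathological"}.
#' @export
classify_parameter <- function(value, parameter, gender = c("female", "male"),
                               ranges = healthy_ranges()) {
  if (length(parameter) != 1 ||
      !parameter %in% c("f0", "jitter", "shimmer", "hnr")) {
    stop("unknown parameter: ", paste(parameter, collapse = ", "),
         call. = FALSE)
  }
  healthy <- switch(parameter,
    f0 = {
      gender <- match.arg(gender)
      iv <- if (gender == "female") ranges$f0_female else ranges$f0_male
      value >= iv[1] & value <= iv[2]
    },
    jitter = value < ranges$jitter_max,
    shimmer = value < ranges$shimmer_max,
    hnr = value > ranges$hnr_min
  )
  ifelse(healthy, "healthy", "pathological")
}

#' Screen an acoustic profile
#'
#' Applies [classify_parameter()] to all four parameters and aggregates
#' them into an overall verdict. The default aggregation,
#' \code{"any_abnormal"}, flags the voice as pathological as soon as one
#' parameter falls outside its healthy range — the clinically conservative
#' choice for a screening instrument. \code{"majority"} requires at least
#' three abnormal parameters (ties of 2-2 count as healthy).
#'
#' @param profile an [acoustic_profile()].
#' @param meta a [subject_meta()] (gender resolves the F0 range).
#' @param ranges a [healthy_ranges()] object.
#' @param overall_rule \code{"any_abnormal"} (default) or \code{"majority"}.
#' @return An object of class \code{screening_report}: list with
#'   \code{verdicts} (named character vector over the four parameters),
#'   \code{overall}, \code{overall_rule}, \code{profile}, \code{gender}.
#' @export
screen <- function(profile, meta = subject_meta("female"),
                   ranges = healthy_ranges(),
                   overall_rule = c("any_abnormal", "majority")) {
  stopifnot(inherits(profile, "acoustic_profile"))
  overall_rule <- match.arg(overall_rule)
  gender <- if (inherits(meta, "subject_meta")) meta$gender else as.character(meta)
  if (!gender %in% c("female", "male")) {
    stop("screening requires a known gender (F0 range is gendered)",
         call. = FALSE)
  }
  verdicts <- c(
    f0 = classify_parameter(profile$f0, "f0", gender, ranges),
    jitter = classify_parameter(profile$jitter, "jitter", gender, ranges),
    shimmer = classify_parameter(profile$shimmer, "shimmer", gender, ranges),
    hnr = classify_parameter(profile$hnr, "hnr", gender, ranges)
  )
  n_abn <- sum(verdicts == "pathological")
  overall <- switch(overall_rule,
    any_abnormal = if (n_abn >= 1) "pathological" else "healthy",
    majority = if (n_abn >= 3) "pathological" else "healthy"
  )
  structure(list(verdicts = verdicts, overall = overall,
                 overall_rule = overall_rule, profile = profile,
                 gender = gender),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Rule-based voice screen (", x$gender, ")\n", sep = "")
  p <- x$profile
  vals <- c(sprintf("%g Hz", p$f0), sprintf("%.3f %%", p$jitter),
            sprintf("%.3f dB", p$shimmer), sprintf("%.2f dB", p$hnr))
  for (i in seq_along(x$verdicts)) {
    cat(sprintf("  %-8s %-12s %s\n", names(x$verdicts)[i], vals[i],
                x$verdicts[i]))
  }
  cat(sprintf("  overall: %s (rule: %s)\n", x$overall, x$overall_rule))
  invisible(x)
}

#' Band a Voice Handicap Index score
#'
#' The 30-item VHI self-perception questionnaire scores 0-180; the score is
#' banded as no / mild / moderate / severe perceived voice disorder at the
#' conventional cut points 32, 43 and 60.
#'
#' @param score integer score in [0, 180] (vectorised).
#' @return \code{"none"}, \code{"mild"}, \code{"moderate"} or
#'   \code{"severe"}.
#' @export
classify_vhi <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 180)) {
    stop("VHI score must be in [0, 180]", call. = FALSE)
  }
  as.character(cut(score, breaks = c(-1, 32, 43, 60, 180),
                   labels = c("none", "mild", "moderate", "severe")))
}

#' Band a Reflux Symptom Index score
#'
#' The RSI questionnaire scores 0-45; scores of 13 and above indicate
#' perceived laryngopharyngeal reflux.
#'
#' @param score integer score in [0, 45] (vectorised).
#' @return \code{"none"} or \code{"perceived"}.
#' @export
classify_rsi <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 45)) {
    stop("RSI score must be in [0, 45]", call. = FALSE)
  }
  ifelse(score <= 12, "none", "perceived")
}
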