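#' Analyze a sustained-vowel recording
#'
#' Runs the full measurement pipeline on one recording: optional
#' resampling to the pipeline rate, validation, Yin pitch tracking over the
#' demographic search band, pitch-synchronous cycle extraction, and the
#' four parameter estimates (F0, jitter, shimmer, HNR).
#'
#' @param rec a [voice_recording()] (any rate; resampled internally) or a
#'   path to a WAV file.
#' @param meta a [subject_meta()]; gender selects the F0 search band.
#' @param pipeline_rate operating rate in Hz (default 8000).
#' @param min_duration validation minimum in seconds (default 5); use 0 to
#'   analyze short signals anyway.
#' @param hnr_method \code{"cepstral"} or \code{"autocorrelation"}.
#' @param trim trim leading/trailing silence first (default \code{FALSE}).
#' @param frame_s,hop_s,yin_threshold pitch-analysis parameters, see
#'   [estimate_pitch_track()].
#' @return An object of class \code{voice_analysis}: list with
#'   \code{profile} (an [acoustic_profile()]), \code{validation},
#'   \code{track}, \code{cycles}, \code{hnr_detail}, \code{meta},
#'   \code{rec}.
#' @examples
#' v <- synthesize_vowel(synthesis_spec(f0 = 220, jitter = 1.5,
#'                                      shimmer = 0.4, hnr = 18, seed = 42))
#' a <- analyze_voice(v$recording, subject_meta("female"))
#' a
#' screen(a$profile, subject_meta("female"))
#' @export
analyze_voice <- function(rec, meta = subject_meta(),
                          pipeline_rate = 8000, min_duration = 5.0,
                          hnr_method = c("cepstral", "autocorrelation"),
                          trim = FALSE, frame_s = 0.040, hop_s = 0.010,
                          yin_threshold = 0.20) {
  hnr_method <- match.arg(hnr_method)
  if (is.character(rec)) rec <- load_recording(rec)
  stopifnot(inherits(rec, "voice_recording"))
  rec <- resample_to_pipeline_rate(rec, pipeline_rate)
  if (trim) rec <- trim_silence(rec)
  validation <- validate_recording(rec, min_duration = min_duration)

  band <- default_search_band(meta)
  track <- estimate_pitch_track(rec, band, frame_s = frame_s, hop_s = hop_s,
                                threshold = yin_threshold)
  # median over voiced frames: immune to the occasional octave outlier
  f0 <- summarize_f0(track, stat = "median")
  cycles <- extract_cycles(rec, track)
  hnr <- hnr_db(rec, f0, cycles = cycles, method = hnr_method)
  profile <- acoustic_profile(
    f0 = f0,
    jitter = jitter_percent(cycles),
    shimmer = shimmer_db(cycles),
    hnr = hnr$hnr
  )
  structure(
    list(profile = profile, validation = validation, track = track,
         cycles = cycles, hnr_detail = hnr, meta = meta, rec = rec),
    class = "voice_analysis"
  )
}

#' @export
print.voice_analysis <- function(x, ...) {
  cat("Acoustic voice analysis\n")
  cat(sprintf("  recording: %.2f s at %g Hz%s\n", x$rec$duration, x$rec$rate,
              if (!x$validation$usable) {
                paste0(" [NOT USABLE: ",
                       paste(x$validation$reasons, collapse = ", "), "]")
              } else ""))
  p <- x$profile
  cat(sprintf("  F0      %6g Hz\n", p$f0))
  cat(sprintf("  jitter  %6.3f %%\n", p$jitter))
  cat(sprintf("  shimmer %6.3f dB\n", p$shimmer))
  cat(sprintf("  HNR     %6.2f dB\n", p$hnr))
  invisible(x)
}

#' @export
summary.voice_analysis <- function(object, ...) {
  print(object)
  tr <- object$track
  cat(sprintf("  voiced frames: %d / %d (%.0f%%)\n",
              sum(tr$voiced_flags), length(tr$voiced_flags),
              100 * mean(tr$voiced_flags)))
  cat(sprintf("  cycles extracted: %d (mean period %.3f ms)\n",
              object$cycles$n_cycles, 1000 * mean(object$cycles$periods)))
  if (object$hnr_detail$floored) {
    cat("  note: HNR hit the floor value (no harmonic structure found)\n")
  }
  invisible(object)
}

#' @export
plot.voice_analysis <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  t <- seq_along(x$rec$samples) / x$rec$rate
  graphics::plot(t, x$rec$samples, type = "l", xlab = "time (s)",
                 ylab = "amplitude", main = "waveform", ...)
  tr <- x$track
  f0 <- ifelse(tr$voiced_flags, tr$f0_frames, NA)
  graphics::plot(tr$frame_times, f0, type = "p", pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "F0 (Hz)",
                 main = "pitch track (voiced frames)")
  invisible(x)
}

#' Analyze and screen a batch of recordings
#'
#' The batch driver behind the command line: analyzes each WAV, skips files
#' that fail validation (recording their failure reasons), screens each
#' usable profile, and returns one row per input.
#'
#' @param paths character vector of WAV paths.
#' @param metadata data frame with columns \code{id} (basename or path),
#'   \code{gender}, optionally \code{label}.
#' @param ranges a [healthy_ranges()] object.
#' @param overall_rule aggregation rule for [screen()].
#' @param ... further arguments passed to [analyze_voice()].
#' @return A data frame with id, gender, duration, the four measured
#'   values, the four verdicts, the overall verdict and an \code{excluded}
#'   column carrying validation failure reasons (empty when analyzed).
#' @export
analyze_batch <- function(paths, metadata, ranges = healthy_ranges(),
                          overall_rule = "any_abnormal", ...) {
  rows <- lapply(paths, function(p) {
    id <- basename(p)
    m <- metadata[match(id, metadata$id), , drop = FALSE]
    if (nrow(m) == 0 || is.na(m$id[1])) {
      m <- metadata[match(p, metadata$id), , drop = FALSE]
    }
    base <- data.frame(id = id, gender = NA_character_,
                       label = NA_character_,
                       duration = NA_real_, f0 = NA_real_,
                       jitter = NA_real_, shimmer = NA_real_,
                       hnr = NA_real_, f0_verdict = NA_character_,
                       jitter_verdict = NA_character_,
                       shimmer_verdict = NA_character_,
                       hnr_verdict = NA_character_,
                       overall = NA_character_, excluded = "",
                       stringsAsFactors = FALSE)
    if (nrow(m) == 0 || is.na(m$id[1])) {
      base$excluded <- "missing_metadata"
      return(base)
    }
    meta <- subject_meta(m$gender[1],
                         label = if ("label" %in% names(m)) m$label[1]
                                 else "unknown")
    base$gender <- meta$gender
    base$label <- meta$clinician_label
    rec <- tryCatch(load_recording(p), error = function(e) NULL)
    if (is.null(rec)) {
      base$excluded <- "unreadable"
      return(base)
    }
    rec <- resample_to_pipeline_rate(rec)
    base$duration <- rec$duration
    v <- validate_recording(rec)
    if (!v$usable) {
      base$excluded <- paste(v$reasons, collapse = ";")
      return(base)
    }
    a <- tryCatch(analyze_voice(rec, meta, ...), error = function(e) NULL)
    if (is.null(a)) {
      base$excluded <- "analysis_failed"
      return(base)
    }
    rep <- screen(a$profile, meta, ranges, overall_rule)
    base$f0 <- a$profile$f0
    base$jitter <- a$profile$jitter
    base$shimmer <- a$profile$shimmer
    base$hnr <- a$profile$hnr
    base$f0_verdict <- rep$verdicts[["f0"]]
    base$jitter_verdict <- rep$verdicts[["jitter"]]
    base$shimmer_verdict <- rep$verdicts[["shimmer"]]
    base$hnr_verdict <- rep$verdicts[["hnr"]]
    base$overall <- rep$overall
    base
  })
  do.call(rbind, rows)
}
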