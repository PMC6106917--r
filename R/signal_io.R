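#' Construct a voice recording
#'
#' The basic container of the pipeline: a sampled, dimensionless waveform
#' (nominally in [-1, 1]) with its sampling rate. Duration is derived from
#' the sample count.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class \code{voice_recording} with fields
#'   \code{samples}, \code{rate}, \code{duration}.
#' @export
voice_recording <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("recording has no samples", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("sampling rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate, duration = length(samples) / rate),
    class = "voice_recording"
  )
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording: %.3f s at %g Hz (%d samples)>\n",
              x$duration, x$rate, length(x$samples)))
  invisible(x)
}

#' Subject metadata
#'
#' Gender drives the F0 search band and the gendered healthy ranges; age is
#' accepted for completeness but unused by the default configuration; the
#' clinician label is the reference standard for evaluation runs.
#'
#' @param gender \code{"female"}, \code{"male"} or \code{"unknown"}.
#' @param age years, optional.
#' @param label clinician label: \code{"healthy"}, \code{"pathological"} or
#'   \code{"unknown"}.
#' @return An object of class \code{subject_meta}.
#' @export
subject_meta <- function(gender = c("unknown", "female", "male"), age = NA,
                         label = c("unknown", "healthy", "pathological")) {
  gender <- match.arg(gender)
  label <- match.arg(label)
  structure(list(gender = gender, age = age, clinician_label = label),
            class = "subject_meta")
}

#' Load a voice recording from a WAV file
#'
#' Reads the file, averages multichannel content down to mono, and returns a
#' [voice_recording()] at the file's native rate (resampling to the pipeline
#' rate is a separate, explicit step: [resample_to_pipeline_rate()]).
#'
#' @param path path to a RIFF/WAVE file.
#' @return A [voice_recording()].
#' @export
load_recording <- function(path) {
  w <- read_wav(path)
  voice_recording(rowMeans(w$samples), w$rate)
}

#' Resample a recording to the pipeline rate
#'
#' The analysis operates at a fixed rate (8000 Hz by default). Resampling is
#' polyphase with band-limiting below the new Nyquist before decimation; a
#' recording already at the target rate is returned unchanged.
#'
#' @param rec a [voice_recording()].
#' @param target_rate target sampling rate in Hz, default 8000.
#' @return A [voice_recording()] at \code{target_rate}.
#' @export
resample_to_pipeline_rate <- function(rec, target_rate = 8000) {
  stopifnot(inherits(rec, "voice_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      target_rate <= 0) {
    stop("target_rate must be a single positive number", call. = FALSE)
  }
  if (rec$rate == target_rate) return(rec)
  frac <- ratio_integers(target_rate, rec$rate)
  y <- signal::resample(rec$samples, frac[1], frac[2])
  n_out <- round(length(rec$samples) * target_rate / rec$rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, rep(0, n_out - length(y)))
  voice_recording(y, target_rate)
}

# smallest integer p/q with p/q == a/b
ratio_integers <- function(a, b) {
  scale <- 1
  while (abs(a * scale - round(a * scale)) > 1e-9 ||
         abs(b * scale - round(b * scale)) > 1e-9) {
    scale <- scale * 10
  }
  p <- round(a * scale)
  q <- round(b * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Validate a recording against the acquisition requirements
#'
#' A usable sustained-vowel recording must be at least \code{min_duration}
#' seconds long, must not be clipped, and must not be (near-)silent.
#' Short files are the most common corruption in field use (the vocalization
#' stops before five seconds); clipping and silence catch microphone faults.
#'
#' @param rec a [voice_recording()].
#' @param min_duration minimum duration in seconds (default 5).
#' @param clip_fraction_max maximum tolerated fraction of samples at
#'   |x| >= 0.999 before the recording counts as clipped (default 0.01).
#' @param silence_rms_floor RMS floor below which the recording counts as
#'   silent (default 1e-4).
#' @return A list with \code{usable} (logical) and \code{reasons}
#'   (character vector drawn from \code{"too_short"}, \code{"clipped"},
#'   \code{"silent"}); \code{usable} is \code{TRUE} iff no reason applies.
#' @export
validate_recording <- function(rec, min_duration = 5.0,
                               clip_fraction_max = 0.01,
                               silence_rms_floor = 1e-4) {
  stopifnot(inherits(rec, "voice_recording"))
  reasons <- character(0)
  # one sample period of slack so a file that is 5 s to the sample passes
  if (rec$duration < min_duration - 1 / rec$rate) reasons <- c(reasons, "too_short")
  if (mean(abs(rec$samples) >= 0.999) > clip_fraction_max) {
    reasons <- c(reasons, "clipped")
  }
  if (sqrt(mean(rec$samples^2)) < silence_rms_floor) {
    reasons <- c(reasons, "silent")
  }
  list(usable = length(reasons) == 0, reasons = reasons)
}

#' Trim leading and trailing low-energy samples
#'
#' Optional pre-processing step, off by default in [analyze_voice()]:
#' removes leading/trailing stretches whose short-window RMS falls below a
#' fraction of the overall RMS.
#'
#' @param rec a [voice_recording()].
#' @param threshold fraction of overall RMS below which edge windows are
#'   treated as silence (default 0.05).
#' @param window_s RMS window in seconds (default 0.02).
#' @return A trimmed [voice_recording()] (unchanged if nothing qualifies).
#' @export
trim_silence <- function(rec, threshold = 0.05, window_s = 0.02) {
  stopifnot(inherits(rec, "voice_recording"))
  w <- max(1L, round(window_s * rec$rate))
  n <- length(rec$samples)
  nw <- n %/% w
  if (nw < 2) return(rec)
  m <- matrix(rec$samples[seq_len(nw * w)], nrow = w)
  rms <- sqrt(colMeans(m^2))
  keep <- rms >= threshold * sqrt(mean(rec$samples^2))
  if (!any(keep)) return(rec)
  first <- (which(keep)[1] - 1) * w + 1
  last <- min(n, max(which(keep)) * w)
  voice_recording(rec$samples[first:last], rec$rate)
}
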