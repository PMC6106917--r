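#' Bundled clinical-study tables
#'
#' The package ships, as plain CSV, the published evaluation tables of a
#' clinical study of an m-health voice-screening app on a 208-subject
#' cohort (58 healthy, 150 pathological): per-parameter measurements and
#' verdicts for repeat recordings (reliability), measurements of the same
#' signals on four Android devices with their printed dispersion rows
#' (portability), the rule-based classification performance per parameter,
#' and the cohort composition and questionnaire-band counts. They serve as
#' reference inputs for the consistency checks in the test suite and the
#' acceptance script.
#'
#' Four obvious typographical slips in the published portability tables
#' were corrected during transcription: an HNR of "32.l" read as 32.1, an
#' HNR of "22,61" read as 22.61, a shimmer of "1.,5" read as 1.05 (the
#' printed dispersion of 0.02 confirms it), and a printed dispersion of
#' "0.084" read as 0.84 (the four measurements it summarises have sample
#' standard deviation 0.836). Two printed verdict cells contradict the
#' published healthy ranges and are flagged in the \code{anomaly} column
#' rather than silently changed: one repeat-recording F0 of 261 Hz
#' (female) printed pathological, and two device F0 cells of 277 and 276 Hz
#' (female) printed pathological, all inside the 189-280 Hz healthy range.
#' Likewise two printed dispersion cells (both shimmer) are inconsistent
#' with the sample standard deviation of their own four measurements and
#' carry an \code{anomaly} flag in the dispersion table.
#'
#' @param name one of \code{"reliability_recordings"},
#'   \code{"portability_measurements"}, \code{"portability_dispersion"},
#'   \code{"rule_performance"}, \code{"cohort_summary"},
#'   \code{"vhi_bands"}, \code{"rsi_bands"}, \code{"reliability_summary"}.
#' @return A data frame.
#' @export
study_table <- function(name = c("reliability_recordings",
                                 "portability_measurements",
                                 "portability_dispersion",
                                 "rule_performance", "cohort_summary",
                                 "vhi_bands", "rsi_bands",
                                 "reliability_summary")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "voxscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = if (name == "portability_dispersion") {
                          c(devst_printed = "character",
                            anomaly = "character")
                        } else NA)
  if ("anomaly" %in% names(df)) df$anomaly[is.na(df$anomaly)] <- ""
  if ("note" %in% names(df)) df$note[is.na(df$note)] <- ""
  if (name == "portability_dispersion") df$anomaly <- df$anomaly == "true"
  df
}

#' Long-format verdict cells from the bundled tables
#'
#' Reshapes the reliability and portability tables into one row per printed
#' (value, parameter, gender, verdict) cell, for wholesale re-checking
#' against [classify_parameter()].
#'
#' @return A data frame with columns \code{source}, \code{voice_id},
#'   \code{parameter}, \code{gender}, \code{value}, \code{verdict_printed},
#'   \code{anomaly} (\code{TRUE} where the printed verdict is a documented
#'   contradiction of the published ranges).
#' @export
study_verdict_cells <- function() {
  rel <- study_table("reliability_recordings")
  por <- study_table("portability_measurements")
  long_one <- function(df, source) {
    do.call(rbind, lapply(c("f0", "jitter", "shimmer", "hnr"), function(p) {
      data.frame(source = source, voice_id = df$voice_id, parameter = p,
                 gender = df$gender, value = df[[p]],
                 verdict_printed = df[[paste0(p, "_verdict")]],
                 anomaly = df$anomaly == p, stringsAsFactors = FALSE)
    }))
  }
  rbind(long_one(rel, "reliability"), long_one(por, "portability"))
}
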