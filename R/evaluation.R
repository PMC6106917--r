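#' Confusion counts for a verdict sequence
#'
#' Tallies predictions against reference labels with \emph{pathological} as
#' the positive class: TP = pathological correctly flagged, TN = healthy
#' correctly cleared, FP = healthy flagged, FN = pathological missed.
#'
#' @param predicted character vector of \code{"healthy"}/\code{"pathological"}.
#' @param truth reference labels, same length and levels.
#' @return An object of class \code{confusion_counts}: list with integer
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  lv <- c("healthy", "pathological")
  if (!all(predicted %in% lv) || !all(truth %in% lv)) {
    stop("labels must be 'healthy' or 'pathological'", call. = FALSE)
  }
  confusion_counts(
    tp = sum(predicted == "pathological" & truth == "pathological"),
    tn = sum(predicted == "healthy" & truth == "healthy"),
    fp = sum(predicted == "pathological" & truth == "healthy"),
    fn = sum(predicted == "healthy" & truth == "pathological")
  )
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d, TN %d, FP %d, FN %d>\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), each as a percentage. A metric whose
#' denominator is zero raises an error naming the metric unless
#' \code{allow_undefined = TRUE}, in which case it is returned as \code{NA}.
#'
#' @param c a \code{confusion_counts} object.
#' @param allow_undefined return \code{NA} instead of failing on a zero
#'   denominator.
#' @return Named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{specificity} in percent.
#' @export
metrics_from_confusion <- function(c, allow_undefined = FALSE) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      if (allow_undefined) return(NA_real_)
      stop("undefined metric: ", what, " has a zero denominator",
           call. = FALSE)
    }
    100 * num / den
  }
  c(accuracy = ratio(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy"),
    sensitivity = ratio(c$tp, c$tp + c$fn, "sensitivity"),
    specificity = ratio(c$tn, c$tn + c$fp, "specificity"))
}

#' Reconstruct confusion counts from published rates
#'
#' Given the class sizes and reported sensitivity/specificity of a
#' classifier, reconstructs the confusion counts: TP = round(P *
#' sensitivity) with FN the complement, TN = round(N * specificity) with FP
#' the complement, using round-half-up on the products. Useful for
#' consistency-checking a published accuracy against its published rates.
#'
#' @param n_pathological,n_healthy class sizes (positive integers).
#' @param sensitivity,specificity rates as fractions in [0, 1].
#' @return A \code{confusion_counts} object.
#' @export
confusion_from_rates <- function(n_pathological, n_healthy,
                                 sensitivity, specificity) {
  if (n_pathological <= 0 || n_healthy <= 0) {
    stop("class sizes must be positive", call. = FALSE)
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("rates must be fractions in [0, 1]", call. = FALSE)
  }
  tp <- round_half_up(n_pathological * sensitivity)
  tn <- round_half_up(n_healthy * specificity)
  confusion_counts(tp = tp, tn = tn,
                   fp = n_healthy - tn, fn = n_pathological - tp)
}

round_half_up <- function(x) floor(x + 0.5)

#' Repeat-recording discordance rate
#'
#' Fraction of recording pairs (two acquisitions of the same subject) whose
#' two overall verdicts disagree — the reliability statistic for a
#' screening instrument applied twice.
#'
#' @param paired_verdicts a two-column matrix/data frame of verdicts, or a
#'   list of length-2 vectors.
#' @return Fraction of discordant pairs in [0, 1].
#' @export
repeatability_rate <- function(paired_verdicts) {
  if (is.list(paired_verdicts) && !is.data.frame(paired_verdicts)) {
    paired_verdicts <- do.call(rbind, paired_verdicts)
  }
  paired_verdicts <- as.matrix(paired_verdicts)
  if (nrow(paired_verdicts) == 0) stop("no verdict pairs", call. = FALSE)
  mean(paired_verdicts[, 1] != paired_verdicts[, 2])
}

#' Cross-device measurement dispersion
#'
#' The sample standard deviation (divisor n - 1) of the same parameter
#' measured on the same signal by several devices — low dispersion means
#' the measurement is portable across hardware.
#'
#' @param values numeric vector of at least 2 measurements.
#' @return Sample standard deviation, same units as the input.
#' @export
device_dispersion <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("dispersion needs at least 2 measurements", call. = FALSE)
  }
  stats::sd(values)
}
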