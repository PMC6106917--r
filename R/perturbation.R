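#' Jitter (relative, percent)
#'
#' Cycle-to-cycle frequency perturbation: the mean absolute difference
#' between consecutive periods, divided by the mean period, expressed as a
#' percentage:
#' \deqn{J = 100 \cdot \frac{\frac{1}{N-1}\sum_{i=1}^{N-1} |T_i - T_{i+1}|}
#'                         {\frac{1}{N}\sum_{i=1}^{N} T_i}}
#' The measure is invariant to the time unit of the periods.
#'
#' @param cycles a [cycle_track()] with at least 2 periods.
#' @return Jitter in percent (>= 0).
#' @export
jitter_percent <- function(cycles) {
  t <- cycles$periods
  n <- length(t)
  if (n < 2) stop("insufficient cycles: jitter needs at least 2 periods",
                  call. = FALSE)
  100 * mean(abs(diff(t))) / mean(t)
}

#' Shimmer (dB)
#'
#' Cycle-to-cycle amplitude perturbation: the mean absolute base-10
#' logarithm of the ratio of consecutive peak-to-peak amplitudes, times 20:
#' \deqn{S = \frac{1}{N-1}\sum_{i=1}^{N-1}
#'           \left| 20 \log_{10} \frac{A_{i+1}}{A_i} \right|}
#' The absolute value is applied per term, and the measure is invariant to
#' the amplitude unit.
#'
#' @param cycles a [cycle_track()] with at least 2 strictly positive
#'   amplitudes.
#' @return Shimmer in dB (>= 0).
#' @export
shimmer_db <- function(cycles) {
  a <- cycles$amplitudes
  n <- length(a)
  if (n < 2) stop("insufficient cycles: shimmer needs at least 2 amplitudes",
                  call. = FALSE)
  if (any(a <= 0)) {
    stop("degenerate amplitude: shimmer requires all amplitudes > 0",
         call. = FALSE)
  }
  mean(abs(20 * diff(log10(a))))
}
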