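#' Demographic F0 search band
#'
#' Vocal-fold vibration rates depend strongly on gender (and more weakly on
#' age), so the pitch search is restricted to a demographic band. The bands
#' are deliberately generous: they strictly contain the gendered healthy
#' ranges (female 189-280 Hz, male 104-158 Hz) with wide pathological
#' margins, so a grossly abnormal F0 is still measured rather than clamped.
#'
#' @param meta a [subject_meta()]; only \code{gender} is used by default.
#' @return A list with \code{fmin}, \code{fmax} in Hz.
#' @export
default_search_band <- function(meta = subject_meta()) {
  gender <- if (inherits(meta, "subject_meta")) meta$gender else as.character(meta)
  band <- switch(gender,
    female = c(60, 600),
    male = c(50, 500),
    c(50, 600)
  )
  f0_search_band(band[1], band[2])
}

#' @rdname default_search_band
#' @param fmin,fmax band edges in Hz; 0 < fmin < fmax.
#' @export
f0_search_band <- function(fmin, fmax) {
  if (!(fmin > 0 && fmax > fmin)) {
    stop("need 0 < fmin < fmax for an F0 search band", call. = FALSE)
  }
  list(fmin = fmin, fmax = fmax)
}

#' Frame-wise F0 track via the Yin method
#'
#' Classic Yin: per frame, the difference function of the signal with a
#' lagged copy of itself is computed (here via FFT correlation), normalised
#' to the cumulative-mean-normalised difference function (CMNDF), and the
#' first lag inside the search band whose CMNDF dips below an absolute
#' threshold is selected and refined by parabolic interpolation. Frames
#' where no lag passes the threshold are marked unvoiced (F0 = 0).
#'
#' The signal is low-pass filtered (zero phase, passband edge
#' \code{lp_cutoff}) before the difference function is computed: period
#' perturbation misaligns high harmonics far more than the fundamental
#' region, so tracking on the low band keeps the CMNDF dips deep for
#' perturbed (pathological) voices while plain broadband noise still fails
#' the threshold. The selected lag is refined by parabolic interpolation on
#' the raw difference function (the cumulative normalisation skews the
#' minimum of wide, single-harmonic dips).
#'
#' @param rec a [voice_recording()] at the pipeline rate.
#' @param band search band from [default_search_band()].
#' @param frame_s integration-window length in seconds (default 0.040 —
#'   holds at least two periods at 50 Hz).
#' @param hop_s hop between frames in seconds (default 0.010).
#' @param threshold absolute CMNDF voicing threshold (default 0.20).
#' @param lp_cutoff tracking pre-filter passband edge in Hz (default 1000;
#'   \code{Inf} disables the pre-filter).
#' @return An object of class \code{pitch_track}: list with
#'   \code{frame_times} (s), \code{f0_frames} (Hz, 0 where unvoiced),
#'   \code{voiced_flags}, and the analysis parameters.
#' @references de Cheveigne A., Kawahara H. (2002) YIN, a fundamental
#'   frequency estimator for speech and music. J. Acoust. Soc. Am. 111(4).
#' @export
estimate_pitch_track <- function(rec, band = default_search_band(),
                                 frame_s = 0.040, hop_s = 0.010,
                                 threshold = 0.20, lp_cutoff = 1000) {
  stopifnot(inherits(rec, "voice_recording"))
  fs <- rec$rate
  x <- rec$samples
  if (is.finite(lp_cutoff) && lp_cutoff < fs / 2) {
    x <- fft_lowpass(x, fs, lp_cutoff, min(1.3 * lp_cutoff, fs / 2))
  }
  w <- round(frame_s * fs)              # integration window
  hop <- max(1L, round(hop_s * fs))
  tau_max <- min(floor(fs / band$fmin), w)
  tau_min <- max(2L, floor(fs / band$fmax))
  if (tau_min >= tau_max) stop("search band too narrow at this rate", call. = FALSE)
  flen <- w + tau_max                   # samples needed per frame
  if (length(x) < flen) {
    stop("recording shorter than one analysis frame", call. = FALSE)
  }
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  nfft <- 2^ceiling(log2(2 * flen))

  f0 <- numeric(length(starts))
  voiced <- logical(length(starts))
  for (k in seq_along(starts)) {
    fr <- x[starts[k] + 0:(flen - 1)]
    d <- yin_difference(fr, w, tau_max, nfft)
    cm <- yin_cmndf(d)
    sel <- yin_select_lag(cm, tau_min, tau_max, threshold)
    if (!is.na(sel)) {
      # settle on the local minimum of the raw difference function
      while (sel + 1 <= tau_max && d[sel + 1] < d[sel]) sel <- sel + 1
      while (sel - 1 >= tau_min && d[sel - 1] < d[sel]) sel <- sel - 1
      tau <- parabolic_min(d, sel)
      f0k <- fs / tau
      if (f0k >= band$fmin && f0k <= band$fmax) {
        f0[k] <- f0k
        voiced[k] <- TRUE
      }
    }
  }
  structure(
    list(frame_times = (starts - 1) / fs, f0_frames = f0,
         voiced_flags = voiced, frame_s = frame_s, hop_s = hop_s,
         band = band, rate = fs),
    class = "pitch_track"
  )
}

# Yin difference function d(tau), tau = 1..tau_max, over an integration
# window of w samples, using one FFT-based correlation per frame:
#   d(tau) = r0 + r_tau - 2 * corr(tau)
yin_difference <- function(fr, w, tau_max, nfft) {
  head <- fr[1:w]
  X <- stats::fft(c(fr, rep(0, nfft - length(fr))))
  H <- stats::fft(c(head, rep(0, nfft - w)))
  cc <- Re(stats::fft(X * Conj(H), inverse = TRUE)) / nfft
  corr <- cc[2:(tau_max + 1)]           # lag 1..tau_max
  csq <- cumsum(fr^2)
  r0 <- csq[w]
  r_tau <- csq[(1:tau_max) + w] - csq[1:tau_max]
  pmax(r0 + r_tau - 2 * corr, 0)
}

# cumulative-mean-normalised difference function; index = lag
yin_cmndf <- function(d) {
  cs <- cumsum(d)
  cm <- d * seq_along(d) / ifelse(cs > 0, cs, 1)
  cm[cs == 0] <- 1
  cm
}

# first lag in [tau_min, tau_max] below threshold, descended to its local
# minimum; NA if no lag qualifies (unvoiced)
yin_select_lag <- function(cm, tau_min, tau_max, threshold) {
  idx <- tau_min:tau_max
  below <- idx[cm[idx] < threshold]
  if (length(below) == 0) return(NA_integer_)
  tau <- below[1]
  while (tau + 1 <= tau_max && cm[tau + 1] < cm[tau]) tau <- tau + 1
  tau
}

# sub-sample minimum of a sampled curve around integer index i
parabolic_min <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
  den <- a - 2 * b + c
  if (den <= 0) return(i)
  i + (a - c) / (2 * den)
}

# sub-sample maximum (same parabola, opposite curvature)
parabolic_max <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
  den <- a - 2 * b + c
  if (den >= 0) return(i)
  i + (a - c) / (2 * den)
}

#' Single F0 value for a recording
#'
#' The mean frame F0 over voiced frames, rounded to the nearest integer Hz
#' (clinical reports quote whole-Hz values). The median is available as an
#' alternative for tracks with rare octave outliers.
#'
#' @param track a \code{pitch_track}.
#' @param stat \code{"mean"} (default) or \code{"median"}.
#' @return Integer-valued F0 in Hz.
#' @export
summarize_f0 <- function(track, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f0 <- track$f0_frames[track$voiced_flags]
  if (length(f0) == 0) stop("no voiced frames in pitch track", call. = FALSE)
  round(if (stat == "mean") mean(f0) else stats::median(f0))
}

#' Pitch-synchronous cycle extraction
#'
#' Marks one glottal excitation epoch per cycle and measures the
#' cycle-to-cycle periods and amplitudes. Marking operates on the
#' linear-prediction residual of the waveform (the vocal-tract resonances
#' are whitened, so each excitation appears as a sharp pulse free of the
#' formant ringing that would otherwise pull peaks toward regularity),
#' band-limited-upsampled eightfold for sub-sample timing: starting from
#' the strongest residual peak in the first expected period, each next mark
#' is the dominant peak in a window of [period/1.4, period*1.4] after the
#' previous one, refined by parabolic interpolation. Periods T_i are the
#' intervals between consecutive marks; cycles whose period deviates from
#' the expected period by more than \code{factor} are discarded as marking
#' errors. When the residual carries essentially no energy (a pure
#' sinusoid is annihilated by its own predictor), marking falls back to the
#' waveform itself.
#'
#' Amplitudes A_i are peak-to-peak extents: each cycle, realigned at
#' sub-sample precision, is projected onto the mean cycle shape and scaled
#' by that template's own peak-to-peak extent. The projection averages
#' measurement noise over the whole cycle instead of sampling it at two
#' extreme points, which keeps shimmer readable in noisy (low-HNR) voices;
#' for a clean signal it coincides with the per-cycle max - min.
#'
#' Cycles are extracted over the longest voiced region (unvoiced gaps
#' shorter than \code{bridge_s} are treated as tracker dropouts and
#' bridged; a sustained vowel should be one region), or over all regions
#' with \code{region = "all"}. A recording whose consecutive cycles do not
#' resemble each other (median inter-cycle correlation below
#' \code{min_corr}, as in unvoiced noise) fails rather than returning
#' meaningless periods.
#'
#' @param rec a [voice_recording()] at the pipeline rate.
#' @param track the \code{pitch_track} for \code{rec}.
#' @param factor allowed deviation factor of a cycle period from the
#'   expected period (default 1.5).
#' @param region \code{"longest"} voiced region (default) or \code{"all"}.
#' @param bridge_s unvoiced gaps up to this many seconds inside a voiced
#'   stretch are bridged (default 1).
#' @param min_corr minimum median correlation between consecutive cycles
#'   (default 0.5).
#' @return An object of class \code{cycle_track}: list with \code{periods}
#'   (s), \code{amplitudes} (peak-to-peak, dimensionless), \code{n_cycles},
#'   and \code{marks} (sub-sample epoch positions, 1-based sample units).
#' @export
extract_cycles <- function(rec, track, factor = 1.5,
                           region = c("longest", "all"), bridge_s = 1,
                           min_corr = 0.5) {
  stopifnot(inherits(rec, "voice_recording"), inherits(track, "pitch_track"))
  region <- match.arg(region)
  if (!any(track$voiced_flags)) {
    stop("insufficient cycles: no voiced frames", call. = FALSE)
  }
  fs <- rec$rate
  x <- rec$samples
  f0_ref <- stats::median(track$f0_frames[track$voiced_flags])
  hop <- max(1L, round(track$hop_s * fs))
  gap_frames <- max(1L, round(bridge_s / track$hop_s))
  runs <- voiced_runs_bridged(track$voiced_flags, gap_frames)
  if (region == "longest") {
    lens <- runs[, 2] - runs[, 1]
    runs <- runs[which.max(lens), , drop = FALSE]
  }

  q <- 8L
  y <- lp_residual(x)
  if (stats::var(y) < 1e-4 * stats::var(x)) y <- x
  if (abs(min(y)) > abs(max(y))) y <- -y
  yu <- fft_upsample(y, q)
  xu <- fft_upsample(x, q)

  periods <- numeric(0)
  amplitudes <- numeric(0)
  marks_all <- numeric(0)
  corr_all <- numeric(0)
  for (r in seq_len(nrow(runs))) {
    s0 <- (runs[r, 1] - 1) * hop + 1
    s1 <- min(length(x), (runs[r, 2] - 1) * hop + round(track$frame_s * fs))
    marks <- mark_epochs(yu, q, s0, s1, fs / f0_ref)
    if (length(marks) < 4) next
    res <- cycle_measures(xu, yu, q, marks, fs, f0_ref)
    exp_p <- 1 / f0_ref
    ok <- res$periods >= exp_p / factor & res$periods <= exp_p * factor
    periods <- c(periods, res$periods[ok])
    amplitudes <- c(amplitudes, res$amplitudes[ok])
    corr_all <- c(corr_all, res$corr[ok])
    marks_all <- c(marks_all, marks)
  }
  if (length(periods) < 3) {
    stop("insufficient cycles: fewer than 3 usable cycles", call. = FALSE)
  }
  if (stats::median(corr_all) < min_corr) {
    stop("insufficient cycles: consecutive cycles do not repeat ",
         "(median correlation ", round(stats::median(corr_all), 2),
         " < ", min_corr, ")", call. = FALSE)
  }
  cycle_track(periods, amplitudes, marks = marks_all)
}

# peak marking on the upsampled residual between samples s0..s1 (original
# grid); p0 is the expected period in original samples
mark_epochs <- function(yu, q, s0, s1, p0, window_factor = 1.4) {
  u0 <- (s0 - 1) * q + 1
  u1 <- min(length(yu), (s1 - 1) * q + 1)
  p0q <- p0 * q
  w_end <- min(u1, u0 + ceiling(p0q) - 1)
  if (w_end - u0 < 3) return(numeric(0))
  m <- u0 + which.max(yu[u0:w_end]) - 1   # earliest of equal maxima
  marks <- (parabolic_max(yu, m) - 1) / q + 1
  repeat {
    lo <- m + max(2L, floor(p0q / window_factor))
    hi <- m + ceiling(p0q * window_factor)
    if (hi > u1) break
    m <- lo + which.max(yu[lo:hi]) - 1
    marks <- c(marks, (parabolic_max(yu, m) - 1) / q + 1)
  }
  marks
}

# periods, template-projected amplitudes and inter-cycle correlation from
# sub-sample marks; xu is the upsampled waveform, yu the upsampled
# whitened (residual) signal the marks were found on
cycle_measures <- function(xu, yu, q, marks, fs, f0_ref) {
  n_cyc <- length(marks) - 1
  periods <- diff(marks) / fs
  L <- max(4L, floor(0.85 * fs / f0_ref))
  # cycle segments sampled at the original rate, realigned at each mark
  grab <- function(src) {
    segs <- matrix(0, nrow = L, ncol = n_cyc)
    nu <- length(src)
    for (i in seq_len(n_cyc)) {
      idx <- round((marks[i] - 1) * q) + 1 + q * (0:(L - 1))
      idx[idx > nu] <- nu
      segs[, i] <- src[idx]
    }
    segs
  }
  segs_w <- grab(xu)
  # scale factors come from the whitened domain, where the additive noise
  # is flat and the matched-filter projection attains its best averaging
  segs_r <- grab(yu)
  tr <- rowMeans(segs_r)
  denom <- sum(tr^2)
  if (denom <= 0) {
    return(list(periods = periods, amplitudes = rep(0, n_cyc),
                corr = rep(0, n_cyc)))
  }
  a <- pmax(colSums(segs_r * tr) / denom, 1e-12)
  # calibrate to the waveform's peak-to-peak extent
  tw <- rowMeans(segs_w)
  p2p <- max(tw) - min(tw)
  tn <- tw - mean(tw)
  segc <- segs_w - rep(colMeans(segs_w), each = L)
  cors <- colSums(segc * tn) /
    pmax(sqrt(colSums(segc^2) * sum(tn^2)), .Machine$double.xmin)
  list(periods = periods, amplitudes = a * p2p, corr = cors)
}

#' Construct a cycle track
#'
#' @param periods cycle periods T_i in seconds (all > 0).
#' @param amplitudes peak-to-peak amplitudes A_i (same length, all >= 0).
#' @param marks optional cycle-mark positions (sample units).
#' @return An object of class \code{cycle_track}.
#' @export
cycle_track <- function(periods, amplitudes, marks = NULL) {
  periods <- as.numeric(periods)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(periods)) {
    stop("periods and amplitudes must share one length", call. = FALSE)
  }
  if (any(periods <= 0)) stop("all cycle periods must be > 0", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(periods = periods, amplitudes = amplitudes,
                 n_cycles = length(periods), marks = marks),
            class = "cycle_track")
}

#' @export
print.cycle_track <- function(x, ...) {
  cat(sprintf("<cycle_track: %d cycles, mean period %.3f ms>\n",
              x$n_cycles, 1000 * mean(x$periods)))
  invisible(x)
}

# frame index ranges [start, end] of voiced runs, with unvoiced gaps of up
# to gap_frames bridged (tracker dropouts inside a sustained vowel)
voiced_runs_bridged <- function(v, gap_frames = 0L) {
  v2 <- v
  if (gap_frames > 0) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    inner <- which(!r$values & r$lengths <= gap_frames &
                     seq_along(r$values) > 1 &
                     seq_along(r$values) < length(r$values))
    for (k in inner) v2[starts[k]:ends[k]] <- TRUE
  }
  r <- rle(v2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts, ends)[r$values, , drop = FALSE]
}
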