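#' Harmonics-to-noise ratio of a sustained vowel
#'
#' Default method is spectral/cepstral comb-liftering in the style of
#' de Krom (1993): per analysis segment the Hann-windowed log power
#' spectrum is transformed to the cepstrum, the rahmonics (cepstral peaks
#' at multiples of 1/f0, which carry the harmonic comb) are liftered out,
#' and the back-transformed spectrum gives the noise-floor estimate. The
#' floor's overall level is re-calibrated on the between-harmonics bins
#' (exponentiating a liftered log spectrum otherwise underestimates noise
#' power, because the mean of a log is below the log of a mean). Noise
#' energy is the floor's energy — the observed power between harmonics plus
#' the interpolated floor beneath them; harmonic energy is total energy
#' minus noise energy, floored at 0; HNR = 10 log10(H/N). Segment energies
#' (default two-second segments, 50\% overlap) are pooled before the ratio.
#'
#' Cycle-to-cycle period and amplitude perturbation smear the harmonic
#' lines into sidebands that a spectral method cannot distinguish from
#' noise. When a [cycle_track()] with epoch marks is supplied, the signal
#' is first pitch-synchronously normalised — every cycle is resampled to
#' the median period and rescaled to the median amplitude — which
#' re-sharpens the harmonics while leaving additive noise broadband, so the
#' estimate reflects the additive noise rather than the perturbation.
#' [analyze_voice()] passes its extracted cycles automatically.
#'
#' An autocorrelation alternative (the method Praat popularised) is
#' available via \code{method = "autocorrelation"}: per segment the
#' normalised autocorrelation peak r near the expected lag 1/f0 gives
#' HNR = 10 log10(r / (1 - r)).
#'
#' @param rec a [voice_recording()] at the pipeline rate.
#' @param f0 fundamental frequency in Hz (> 0).
#' @param cycles optional [cycle_track()] with marks, enabling
#'   pitch-synchronous normalisation (cepstral method only).
#' @param method \code{"cepstral"} (default) or \code{"autocorrelation"}.
#' @param segment_s analysis segment length in seconds (default 2).
#' @param overlap fractional overlap of consecutive segments (default 0.5).
#' @param lifter_width_ms half-width of the cepstral lifter around each
#'   rahmonic, in milliseconds of quefrency (default 1).
#' @param floor_db value returned (with \code{floored = TRUE}) when no
#'   harmonic energy is detectable, default -10 dB.
#' @return An object of class \code{hnr_result}: list with \code{hnr} (dB),
#'   \code{harmonic_energy}, \code{noise_energy}, \code{floored},
#'   \code{method}.
#' @references de Krom G. (1993) A cepstrum-based technique for determining
#'   a harmonics-to-noise ratio in speech signals. J. Speech Hear. Res. 36.
#' @export
hnr_db <- function(rec, f0, cycles = NULL,
                   method = c("cepstral", "autocorrelation"),
                   segment_s = 2, overlap = 0.5, lifter_width_ms = 1,
                   floor_db = -10) {
  stopifnot(inherits(rec, "voice_recording"))
  method <- match.arg(method)
  if (!is.numeric(f0) || length(f0) != 1 || !is.finite(f0) || f0 <= 0) {
    stop("f0 must be a single positive number", call. = FALSE)
  }
  fs <- rec$rate
  x <- rec$samples
  normalized <- FALSE
  if (method == "cepstral" && !is.null(cycles) && !is.null(cycles$marks) &&
      length(cycles$marks) > 4) {
    # whiten first: the excitation pulse is shape-invariant across cycles,
    # so resampling each cycle to a common period re-sharpens the harmonic
    # comb exactly, whereas warping the formant-coloured waveform would
    # modulate the resonances instead. The harmonic and noise components
    # share the vocal-tract colouring, so inverse filtering leaves their
    # energy ratio intact.
    r <- lp_residual(x)
    if (stats::var(r) >= 1e-4 * stats::var(x)) x <- r
    norm <- pitch_normalize(x, fs, cycles$marks)
    x <- norm$x
    f0 <- norm$f0   # the normalised signal's comb spacing is exact
    normalized <- TRUE
  }
  seg_len <- min(length(x), round(segment_s * fs))
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, max(1L, length(x) - seg_len + 1L), by = hop)

  if (method == "autocorrelation") {
    vals <- vapply(starts, function(s) {
      hnr_segment_acf(x[s + 0:(seg_len - 1)], fs, f0)
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) {
      return(hnr_result(floor_db, 0, 1, TRUE, method))
    }
    h <- mean(vals)
    if (h <= floor_db) return(hnr_result(floor_db, 0, 1, TRUE, method))
    return(hnr_result(h, 10^(h / 10), 1, FALSE, method))
  }

  he <- 0
  ne <- 0
  for (s in starts) {
    e <- hnr_segment_cepstral(x[s + 0:(seg_len - 1)], fs, f0, lifter_width_ms,
                              refine = !normalized,
                              split_alignment = normalized)
    he <- he + e[1]
    ne <- ne + e[2]
  }
  if (ne <= 0) ne <- .Machine$double.xmin
  if (he <= 0 || 10 * log10(he / ne) <= floor_db) {
    return(hnr_result(floor_db, he, ne, TRUE, method))
  }
  hnr_result(10 * log10(he / ne), he, ne, FALSE, method)
}

hnr_result <- function(hnr, he, ne, floored, method) {
  structure(list(hnr = hnr, harmonic_energy = he, noise_energy = ne,
                 floored = floored, method = method),
            class = "hnr_result")
}

#' @export
print.hnr_result <- function(x, ...) {
  cat(sprintf("<hnr_result: %.2f dB (%s)%s>\n", x$hnr, x$method,
              if (x$floored) ", floored" else ""))
  invisible(x)
}

# pitch-synchronous normalisation: resample every cycle between
# consecutive epoch marks to the median period, rescaled to unit relative
# amplitude, so period/amplitude perturbation no longer broadens the
# harmonic lines
pitch_normalize <- function(x, fs, marks) {
  n_cyc <- length(marks) - 1
  periods <- diff(marks)
  L <- max(4L, round(stats::median(periods)))
  q <- 8L
  xu <- fft_upsample(x, q)
  nu <- length(xu)
  # per-cycle rms as the amplitude normaliser (robust, template-free)
  out <- numeric(n_cyc * L)
  scale_ref <- NULL
  for (i in seq_len(n_cyc)) {
    pos <- (marks[i] + periods[i] * (0:(L - 1)) / L - 1) * q + 1
    i0 <- floor(pos)
    frac <- pos - i0
    i0[i0 < 1] <- 1
    i0[i0 > nu - 1] <- nu - 1
    seg <- xu[i0] * (1 - frac) + xu[i0 + 1] * frac
    r <- sqrt(mean(seg^2))
    if (is.null(scale_ref)) scale_ref <- r
    if (r > 0) seg <- seg * (scale_ref / r)
    out[(i - 1) * L + 1:L] <- seg
  }
  list(x = out, f0 = fs / L)
}

# refine f0 by maximising the spectral comb energy over a +/-3% grid, so
# the harmonic windows stay aligned at high harmonic numbers
refine_f0_comb <- function(P, fs, nfft, f0) {
  cand <- f0 * seq(0.97, 1.03, length.out = 121)
  score <- vapply(cand, function(fc) {
    k <- seq_len(max(1, min(20, floor((fs / 2 - fc / 2) / fc))))
    sum(P[pmin(round(k * fc * nfft / fs) + 1, length(P))])
  }, numeric(1))
  i <- which.max(score)
  if (i > 1 && i < length(cand)) {
    a <- score[i - 1]; b <- score[i]; c <- score[i + 1]
    den <- a - 2 * b + c
    if (den < 0) return(cand[i] + (a - c) / (2 * den) * diff(cand[1:2]))
  }
  cand[i]
}

# one segment, cepstral comb-liftering; returns c(harmonic, noise) energy.
# split_alignment (used on pitch-normalised signals, where the true noise
# is whitened and flat): the between-harmonics floor is decomposed into a
# flat additive-noise part and an f^2-shaped part — the spectral footprint
# of sub-sample cycle-alignment error — and only the flat part is counted
# as noise.
hnr_segment_cepstral <- function(seg, fs, f0, lifter_width_ms,
                                 refine = TRUE, split_alignment = FALSE) {
  n <- length(seg)
  w <- hann_window(n)
  xs <- (seg - mean(seg)) * w
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(xs, rep(0, nfft - n)))
  half <- nfft %/% 2 + 1L
  P <- Mod(X)^2
  eps <- max(P) * 1e-14 + .Machine$double.xmin
  logP <- 10 * log10(P + eps)
  if (refine) f0 <- refine_f0_comb(P[seq_len(half)], fs, nfft, f0)

  cep <- Re(stats::fft(logP, inverse = TRUE)) / nfft
  # lifter out rahmonics: quefrency bin q sits at q/fs seconds, so
  # rahmonic k is at bin k*fs/f0
  lift_half <- max(1L, round(lifter_width_ms / 1000 * fs))
  t0_bins <- fs / f0
  k_max <- floor((nfft / 2) / t0_bins)
  if (k_max >= 1) {
    for (k in seq_len(k_max)) {
      centre <- round(k * t0_bins)
      lo <- max(2L, centre - lift_half)
      hi <- min(half, centre + lift_half)
      if (lo <= hi) {
        cep[lo:hi] <- 0
        cep[nfft - (lo:hi) + 2L] <- 0   # mirrored half of the even cepstrum
      }
    }
  }
  logN <- Re(stats::fft(cep))

  # harmonic bins: within a Hann main lobe of each harmonic, widened
  # slightly in proportion to the harmonic number to absorb residual
  # line broadening; everything else is treated as observed noise
  freq <- (seq_len(half) - 1) * fs / nfft
  lobe_hz <- 2 * fs / n
  k_h <- floor((fs / 2) / f0)
  harm <- rep(FALSE, half)
  if (k_h >= 1) {
    for (k in seq_len(k_h)) {
      harm <- harm | abs(freq - k * f0) <= (lobe_hz + 0.003 * k * f0)
    }
  }
  Ph <- P[seq_len(half)]
  logNh <- logN[seq_len(half)]
  noise_bins <- !harm & freq > f0 / 2
  total <- sum(Ph)

  if (split_alignment) {
    # banded medians of the between-harmonics power (median/ln 2 estimates
    # the mean of chi-squared(2) bins robustly), fitted as a + b f^2 over
    # the excitation passband
    fit_bins <- noise_bins & freq < 2800
    if (sum(fit_bins) >= 40) {
      bands <- cut(freq[fit_bins], 10)
      med <- as.numeric(tapply(Ph[fit_bins], bands, stats::median)) / log(2)
      fmid <- as.numeric(tapply(freq[fit_bins], bands, mean))
      ok <- is.finite(med) & is.finite(fmid)
      if (sum(ok) >= 4) {
        X <- cbind(1, fmid[ok]^2)
        beta <- tryCatch(solve(crossprod(X), crossprod(X, med[ok])),
                         error = function(e) NULL)
        if (!is.null(beta)) {
          a <- max(beta[1], 0)
          b <- max(beta[2], 0)
          noise <- min(a * half, total)
          align <- b * sum(pmin(freq, 3200)^2)
          return(c(max(total - noise - align, 0), noise))
        }
      }
    }
  }
  # level-calibrate the liftered floor on the between-harmonics bins. The
  # calibration works on the floor-relative residual logP - logN, which is
  # flat whatever the noise colouring: its median is robust to sideband
  # leakage, and adding 10 log10(1/ln 2) converts the median-matched level
  # of chi-squared(2) bins to their mean. The calibrated floor is then
  # integrated over the whole band, so noise beneath the harmonics is
  # counted once and only once.
  if (any(noise_bins)) {
    delta <- stats::median(logP[seq_len(half)][noise_bins] -
                             logNh[noise_bins]) + 10 * log10(1 / log(2))
    if (is.finite(delta)) logNh <- logNh + delta
  }
  noise <- min(sum(10^(logNh / 10)), total)
  c(max(total - noise, 0), noise)
}

# one segment, normalised autocorrelation at the expected lag; returns dB
hnr_segment_acf <- function(seg, fs, f0) {
  n <- length(seg)
  w <- hann_window(n)
  xs <- (seg - mean(seg)) * w
  nfft <- 2^ceiling(log2(2 * n))
  ac <- Re(stats::fft(Mod(stats::fft(c(xs, rep(0, nfft - n))))^2,
                      inverse = TRUE)) / nfft
  acw <- Re(stats::fft(Mod(stats::fft(c(w, rep(0, nfft - n))))^2,
                       inverse = TRUE)) / nfft
  if (ac[1] <= 0) return(NA_real_)
  # divide out the window's own autocorrelation (Boersma's correction)
  lag0 <- round(fs / f0)
  lo <- max(2L, floor(lag0 * 0.8))
  hi <- min(n - 1L, ceiling(lag0 * 1.25))
  if (lo >= hi) return(NA_real_)
  r <- (ac[(lo:hi) + 1] / acw[(lo:hi) + 1]) / (ac[1] / acw[1])
  i <- which.max(r)
  rmax <- if (i > 1 && i < length(r)) {
    a <- r[i - 1]; b <- r[i]; c <- r[i + 1]
    den <- a - 2 * b + c
    if (den < 0) b - (a - c)^2 / (8 * den) else b
  } else r[i]
  rmax <- min(max(rmax, 1e-9), 1 - 1e-9)
  10 * log10(rmax / (1 - rmax))
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}
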