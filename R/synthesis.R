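#' Specification for a synthetic sustained vowel
#'
#' Describes a quasi-periodic glottal source with controlled mean F0,
#' cycle-period perturbation (jitter target), cycle-amplitude perturbation
#' (shimmer target) and additive broadband noise at a calibrated
#' harmonic-to-noise energy ratio, coloured by a formant filter
#' approximating /a/.
#'
#' @param f0 mean fundamental frequency in Hz, in [50, 600].
#' @param jitter jitter target in percent (>= 0).
#' @param shimmer shimmer target in dB (>= 0).
#' @param hnr harmonic-to-noise target in dB, or \code{Inf} for a noiseless
#'   signal.
#' @param duration seconds (>= 1).
#' @param rate sampling rate in Hz (default 8000).
#' @param formants matrix-like list of \code{c(centre_hz, bandwidth_hz)}
#'   resonators; defaults approximate the vowel /a/.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return An object of class \code{synthesis_spec}.
#' @export
synthesis_spec <- function(f0 = 200, jitter = 0, shimmer = 0, hnr = Inf,
                           duration = 5, rate = 8000,
                           formants = list(c(700, 130), c(1220, 70),
                                           c(2600, 160)),
                           seed = 1) {
  if (f0 < 50 || f0 > 600) stop("f0 must be in [50, 600] Hz", call. = FALSE)
  if (duration < 1) stop("duration must be at least 1 s", call. = FALSE)
  if (jitter < 0 || shimmer < 0) {
    stop("jitter and shimmer targets must be >= 0", call. = FALSE)
  }
  structure(list(f0 = f0, jitter = jitter, shimmer = shimmer, hnr = hnr,
                 duration = duration, rate = rate, formants = formants,
                 seed = seed),
            class = "synthesis_spec")
}

#' Synthesize a sustained vowel with exactly known ground truth
#'
#' One glottal pulse (a windowed band-limited impulse, placed with
#' sub-sample precision) is rendered per cycle, then the pulse train is
#' coloured by a cascade of second-order formant resonators and mixed with
#' formant-filtered white noise. The cycle perturbations are not merely
#' sampled near the targets: the drawn period sequence is affinely rescaled
#' so that the jitter equation evaluated on it equals the jitter target
#' exactly, and the drawn log-amplitude steps are rescaled so the shimmer
#' equation equals the shimmer target exactly; the noise gain is solved so
#' the harmonic-to-noise energy ratio of the emitted signal equals the HNR
#' target exactly. The returned ground truth therefore serves as an
#' analytic oracle for every measurement stage.
#'
#' @param spec a [synthesis_spec()].
#' @return An object of class \code{synthesis_output}: list with
#'   \code{recording} (a [voice_recording()]), \code{truth_cycles} (a
#'   [cycle_track()] of the injected periods and amplitudes),
#'   \code{harmonic_energy}, \code{noise_energy} (energies of the two mixed
#'   components) and \code{spec}.
#' @export
synthesize_vowel <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  with_seed(spec$seed, synthesize_vowel_impl(spec))
}

synthesize_vowel_impl <- function(spec) {
  fs <- spec$rate
  t0 <- 1 / spec$f0
  n_cycles <- ceiling(spec$duration * spec$f0) + 1L
  if (spec$jitter > 0 && n_cycles < 3) {
    stop("infeasible spec: jitter target needs at least 3 cycles",
         call. = FALSE)
  }

  # periods: draw, centre, rescale so the jitter equation hits the target
  d <- stats::rnorm(n_cycles)
  d <- d - mean(d)
  periods <- rep(t0, n_cycles)
  if (spec$jitter > 0) {
    md <- mean(abs(diff(d)))
    if (md == 0) stop("degenerate period draw", call. = FALSE)
    cscale <- spec$jitter * t0 / (100 * md)
    if (cscale * max(abs(d)) > 0.45 * t0) {
      # keep periods strictly positive under extreme draws
      d <- d * (0.45 * t0) / (cscale * max(abs(d)))
      cscale <- spec$jitter * t0 / (100 * mean(abs(diff(d))))
    }
    periods <- t0 + cscale * d
  }

  # amplitudes: rescale log-amplitude deviations to hit the shimmer target
  e <- stats::rnorm(n_cycles)
  db <- rep(0, n_cycles)
  if (spec$shimmer > 0) {
    me <- mean(abs(diff(e)))
    if (me == 0) stop("degenerate amplitude draw", call. = FALSE)
    db <- e * spec$shimmer / me
  }
  amplitudes <- 0.3 * 10^(db / 20)

  # render: band-limited impulse per cycle at its fractional onset
  onsets <- cumsum(c(0, periods[-length(periods)]))   # seconds
  n <- round(spec$duration * fs)
  h <- numeric(n + 4 * fs %/% 100)
  half_len <- 32L
  for (i in seq_len(n_cycles)) {
    pos <- onsets[i] * fs + 1
    k0 <- floor(pos)
    frac <- pos - k0
    idx <- (k0 - half_len):(k0 + half_len)
    keep <- idx >= 1 & idx <= length(h)
    if (!any(keep)) next
    tt <- idx[keep] - k0 - frac
    pulse <- 0.9 * sinc(0.9 * tt) * blackman_taper(tt / (half_len + 1))
    h[idx[keep]] <- h[idx[keep]] + amplitudes[i] * pulse
  }
  h <- formant_filter(h, spec$formants, fs)[seq_len(n)]
  harmonic_energy <- sum(h^2)

  if (is.finite(spec$hnr)) {
    nz <- formant_filter(stats::rnorm(n), spec$formants, fs)
    gain <- sqrt(harmonic_energy / (sum(nz^2) * 10^(spec$hnr / 10)))
    nz <- gain * nz
    noise_energy <- sum(nz^2)
    x <- h + nz
  } else {
    noise_energy <- 0
    x <- h
  }

  # normalise peak level; energies scale together, the ratio is untouched
  peak <- max(abs(x))
  if (peak > 0) {
    g <- 0.7 / peak
    x <- x * g
    harmonic_energy <- harmonic_energy * g^2
    noise_energy <- noise_energy * g^2
    amplitudes_out <- amplitudes * g
  } else {
    amplitudes_out <- amplitudes
  }

  structure(
    list(recording = voice_recording(x, fs),
         truth_cycles = cycle_track(periods, amplitudes_out),
         harmonic_energy = harmonic_energy, noise_energy = noise_energy,
         spec = spec),
    class = "synthesis_output"
  )
}

#' @export
print.synthesis_output <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<synthetic vowel: F0 %g Hz, jitter %g %%, shimmer %g dB, HNR %s, %g s>\n",
    s$f0, s$jitter, s$shimmer,
    if (is.finite(s$hnr)) sprintf("%g dB", s$hnr) else "noiseless",
    s$duration))
  invisible(x)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Blackman taper on u in [-1, 1]
blackman_taper <- function(u) {
  0.42 + 0.5 * cos(pi * u) + 0.08 * cos(2 * pi * u)
}

# cascade of two-pole resonators (centre frequency, bandwidth) in Hz
formant_filter <- function(x, formants, fs) {
  for (f in formants) {
    r <- exp(-pi * f[2] / fs)
    theta <- 2 * pi * f[1] / fs
    a <- c(1, -2 * r * cos(theta), r^2)
    b <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

# evaluate expr with a locally seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a labelled synthetic cohort
#'
#' Emulates a screening-study cohort: healthy members are drawn with all
#' four parameter targets inside the gendered healthy ranges, pathological
#' members with at least one target outside; gender is assigned randomly
#' with a 64.9\% female share, matching the composition typical of voice
#' clinic populations.
#'
#' @param n_healthy,n_pathological group sizes (>= 0).
#' @param seed integer seed.
#' @param duration per-recording duration in seconds (default 5).
#' @param female_share probability that a subject is female (default 0.649).
#' @return A list of entries, each a list with \code{synth} (a
#'   \code{synthesis_output}) and \code{meta} (a [subject_meta()] carrying
#'   the group label).
#' @export
make_cohort <- function(n_healthy, n_pathological, seed = 1, duration = 5,
                        female_share = 0.649) {
  if (n_healthy < 0 || n_pathological < 0) {
    stop("group sizes must be >= 0", call. = FALSE)
  }
  n <- n_healthy + n_pathological
  if (n == 0) return(list())
  params <- with_seed(seed, draw_cohort_params(n_healthy, n_pathological,
                                               female_share))
  lapply(seq_len(n), function(i) {
    p <- params[[i]]
    sp <- synthesis_spec(f0 = p$f0, jitter = p$jitter, shimmer = p$shimmer,
                         hnr = p$hnr, duration = duration,
                         seed = (seed * 1009L + i) %% .Machine$integer.max)
    list(synth = synthesize_vowel(sp),
         meta = subject_meta(p$gender, label = p$label),
         targets = p)
  })
}

draw_cohort_params <- function(n_healthy, n_pathological, female_share) {
  ranges <- healthy_ranges()
  draw_one <- function(label) {
    gender <- if (stats::runif(1) < female_share) "female" else "male"
    f0r <- if (gender == "female") ranges$f0_female else ranges$f0_male
    # healthy targets sit well inside the ranges so that measurement noise
    # cannot flip a verdict
    p <- list(
      gender = gender, label = label,
      f0 = stats::runif(1, f0r[1] + 0.12 * diff(f0r), f0r[2] - 0.12 * diff(f0r)),
      jitter = stats::runif(1, 0.3, 0.8),
      shimmer = stats::runif(1, 0.05, 0.25),
      hnr = stats::runif(1, 24, 28)
    )
    if (label == "pathological") {
      # push one or more parameters clearly outside the healthy range
      which_abn <- sample(c("f0", "jitter", "shimmer", "hnr"),
                          size = sample(1:2, 1))
      if ("f0" %in% which_abn) {
        p$f0 <- if (stats::runif(1) < 0.5) f0r[1] * stats::runif(1, 0.55, 0.8)
                else f0r[2] * stats::runif(1, 1.25, 1.6)
      }
      if ("jitter" %in% which_abn) p$jitter <- stats::runif(1, 1.8, 3.5)
      if ("shimmer" %in% which_abn) p$shimmer <- stats::runif(1, 0.8, 1.6)
      if ("hnr" %in% which_abn) p$hnr <- stats::runif(1, 8, 15)
      p$abnormal <- which_abn
    } else {
      p$abnormal <- character(0)
    }
    p
  }
  c(lapply(seq_len(n_healthy), function(i) draw_one("healthy")),
    lapply(seq_len(n_pathological), function(i) draw_one("pathological")))
}
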