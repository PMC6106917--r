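# Shared zero-phase frequency-domain filtering and interpolation helpers.

# lowpass with a raised-cosine transition between c1 and c2 Hz, zero phase
fft_lowpass <- function(x, fs, c1, c2) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  H <- ifelse(f <= c1, 1,
              ifelse(f >= c2, 0, 0.5 + 0.5 * cos(pi * (f - c1) / (c2 - c1))))
  Re(stats::fft(X * H, inverse = TRUE)) / n
}

# band-limited (sinc) upsampling by an integer factor
fft_upsample <- function(x, q) {
  n <- length(x)
  X <- stats::fft(x)
  N <- n * q
  Y <- complex(real = numeric(N), imaginary = numeric(N))
  half <- n %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(N - half + 2):N] <- X[(n - half + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# linear-prediction residual: whitens the vocal-tract resonances so that
# the glottal excitation epochs stand out as sharp pulses
lp_residual <- function(x, order = 10) {
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker"),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) == 0) return(x)
  r <- as.numeric(stats::filter(x, c(1, -fit$ar), method = "convolution",
                                sides = 1))
  r[is.na(r)] <- 0
  r
}
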