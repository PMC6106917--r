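# Signal fixtures built in code: tones, impulse trains, filtered pulse
# trains with exactly known periods, and temporary WAV files.

make_tone <- function(freq, duration = 5, rate = 8000, amp = 0.5) {
  voice_recording(amp * sin(2 * pi * freq * (0:(duration * rate - 1)) / rate),
                  rate)
}

make_impulse_train <- function(period_samples, duration = 5, rate = 8000,
                               amp = 1.0) {
  n <- round(duration * rate)
  x <- numeric(n)
  idx <- seq(1, n, by = period_samples)
  x[idx] <- amp
  voice_recording(x, rate)
}

# pulse train with an arbitrary integer period sequence, coloured by a
# single resonator — built independently of the synthesis module
make_pulse_vowel <- function(periods_samples, rate = 8000, f_res = 700,
                             bw = 130) {
  onsets <- cumsum(c(1, periods_samples))
  x <- numeric(max(onsets) + 200)
  x[onsets] <- 1
  r <- exp(-pi * bw / rate)
  y <- as.numeric(signal::filter(c(1 - r), c(1, -2 * r * cos(2 * pi * f_res / rate), r^2), x))
  voice_recording(0.7 * y / max(abs(y)), rate)
}

make_white_noise <- function(seed, duration = 5, rate = 8000, amp = 0.3) {
  set.seed(seed)
  voice_recording(amp * stats::rnorm(duration * rate), rate)
}

tmp_wav <- function(samples, rate, bits = 16) {
  path <- tempfile(fileext = ".wav")
  write_wav(samples, rate, path, bits = bits)
  path
}
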