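# Shared fixtures, all generated in code.

# Deterministic sinusoid recording.
tone_recording <- function(freq = 10, fs = 512, duration = 10, n_ch = 1,
                           amp = 1) {
  t <- seq_len(fs * duration) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch), nrow = n_ch,
                 byrow = TRUE)
  recording(data, fs = fs)
}

# Gaussian white-noise recording with optional common component.
noise_recording <- function(fs = 512, duration = 10, n_ch = 4, seed = 1,
                            common = 0.5) {
  with_seed_test(seed, {
    n <- fs * duration
    shared <- rnorm(n)
    data <- t(vapply(seq_len(n_ch), function(i)
      sqrt(1 - common) * rnorm(n) + sqrt(common) * shared, numeric(n)))
    recording(data, fs = fs)
  })
}

# Local seed helper that restores RNG state.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Exact-model spectral profile on the standard analysis grid.
model_profile <- function(psd, freqs = seq(0.5, 40, by = 0.5)) {
  structure(list(freqs = freqs, psd = psd,
                 npsd = psd / sum(psd), range = c(0.5, 40),
                 df = diff(freqs[1:2]), fs = NA, n_segments = NA),
            class = "spectral_profile")
}

# Pink-ish (1/f) noise series via spectral shaping.
shaped_noise <- function(n, fs, exponent, seed = 1) {
  with_seed_test(seed, {
    w <- stats::fft(rnorm(n))
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n
    g <- ifelse(f > 0, f^(-exponent / 2), 0)
    Re(stats::fft(w * g, inverse = TRUE)) / n
  })
}
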