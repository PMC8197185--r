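# Independent oracles and shared fixtures.

# Literal discretization of the windowed short-time DFT: per frame, the
# direct sum over samples for every frequency bin, written as an explicit
# DFT-matrix product. Independent of compute_spectrogram's fft path.
naive_spectrogram_power <- function(signal, window_len = 128, hop = 8) {
  L <- window_len
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  k <- 0:(L - 1)
  E <- exp(-2i * pi * outer(k, 0:(L - 1)) / L) # E[k+1, n+1] = e^{-2pi i k n / L}
  freqs <- ifelse(k > L / 2, k - L, k) * signal$fs / L
  ord <- order(freqs)
  starts <- seq.int(1L, signal$n - L + 1L, by = hop)
  t(vapply(starts, function(s0) {
    seg <- signal$samples[s0:(s0 + L - 1L)]
    (Mod(E %*% (w * seg))^2)[ord]
  }, numeric(L)))
}

# Single constant-velocity point scatterer moving toward the radar.
constant_velocity_signal <- function(v, duration = 2, config = radar_config(),
                                     start_range = 9, eta = 1) {
  n <- round(duration * config$fs)
  times <- (seq_len(n) - 1) / config$fs
  ranges <- start_range - v * times
  baseband_signal(
    eta * config$amplitude * exp(-4i * pi * ranges / config$wavelength),
    fs = config$fs, provenance = "synthetic-tone"
  )
}

# Small shared cohort used by several test files (built once per test run).
tiny_prepared <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(6, 6, rng_seed = 424)
      cache <<- prepare_sequences(ds)
    }
    cache
  }
})

velocity_bin <- function() velocity_resolution(
  compute_spectrogram(constant_velocity_signal(1, duration = 0.5))
)
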