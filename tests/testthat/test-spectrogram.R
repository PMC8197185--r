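test_that("the fft path matches the directly-summed windowed DFT", {
  set.seed(101)
  for (n in c(200, 731, 1500)) {
    sig <- baseband_signal(
      complex(real = rnorm(n), imaginary = rnorm(n)),
      fs = 600
    )
    sp <- compute_spectrogram(sig)
    ref <- naive_spectrogram_power(sig)
    expect_lt(max(abs(sp$power - ref)) / max(ref), 1e-10)
  }
})

test_that("an on-bin complex exponential lands on its labelled velocity", {
  cfg <- radar_config()
  fs <- 600
  # 14 cycles per 128 samples -> 65.625 Hz
  n <- 1024
  f <- 14 * fs / 128
  sig <- baseband_signal(exp(2i * pi * f * (0:(n - 1)) / fs), fs = fs)
  sp <- compute_spectrogram(sig, config = cfg)
  peaks <- sp$velocities[apply(sp$power, 1L, which.max)]
  expect_true(all(abs(peaks - f * cfg$wavelength / 2) < 1e-9))
  expect_equal(f * cfg$wavelength / 2, 0.4099, tolerance = 1e-3)
})

test_that("spectrogram geometry: bins, spacing, frame times, Parseval", {
  sig <- constant_velocity_signal(0.8, duration = 1)
  sp <- compute_spectrogram(sig, window_len = 128, hop = 8)
  expect_equal(ncol(sp$power), 128L)
  expect_equal(unique(round(diff(sp$velocities), 12)),
    round((600 / 128) * sp$config$wavelength / 2, 12))
  # velocities span (-fs/2, fs/2] in Doppler, zero-centred
  expect_equal(max(sp$velocities), doppler_velocity(300, sp$config))
  expect_gt(min(sp$velocities), doppler_velocity(-300, sp$config))
  expect_true(any(sp$velocities == 0))
  expect_equal(unique(round(diff(sp$frame_times), 12)), 8 / 600)
  # per-frame Parseval with the unnormalized DFT: sum over bins = L * windowed energy
  w <- 0.54 - 0.46 * cos(2 * pi * (0:127) / 127)
  j <- 5L
  seg <- sig$samples[(1 + (j - 1) * 8):((j - 1) * 8 + 128)]
  expect_equal(sum(sp$power[j, ]), 128 * sum(Mod(w * seg)^2))
  expect_true(all(sp$power >= 0))
})

test_that("degenerate inputs are rejected or map to zero power", {
  zero <- baseband_signal(complex(real = rep(0, 400), imaginary = rep(0, 400)), fs = 600)
  expect_true(all(compute_spectrogram(zero)$power == 0))
  short <- baseband_signal(complex(real = rnorm(64)), fs = 600)
  expect_error(compute_spectrogram(short), "at least 128")
})

test_that("the gait-cycle period is recovered and the two-cycle crop sized as printed", {
  p <- sample_class_params("young", rng_seed = 2)
  sig <- synthesize_baseband(simulate_walker(p, n_cycles = 5, rng_seed = 3),
    noise_sd = 0.05, rng_seed = 4
  )
  sp <- compute_spectrogram(sig)
  est <- estimate_gait_cycle(sp)
  expect_lt(abs(est$cycle - p$cycle_duration) / p$cycle_duration, 0.10)
  cropped <- select_analysis_interval(sp, n_cycles = 2)
  expect_gte(nrow(cropped$power), 99)
  expect_lte(nrow(cropped$power), 224)
  expect_equal(cropped$cycle_estimate$cycle, est$cycle)
})

test_that("a constant-velocity tone has no gait periodicity to select", {
  sig <- constant_velocity_signal(1.0, duration = 3)
  sp <- compute_spectrogram(sig)
  expect_error(select_analysis_interval(sp), "periodicity")
})
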