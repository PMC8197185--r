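make_spec <- function(power, velocities, fs = 600, hop = 8) {
  structure(
    list(
      frame_times = (seq_len(nrow(power)) - 1) * hop / fs,
      velocities = velocities,
      power = power,
      window_len = length(velocities), hop = hop, fs = fs,
      config = radar_config()
    ),
    class = "gait_spectrogram"
  )
}

test_that("the power-weighted mean velocity evaluates the first moment", {
  v <- c(-1, 0, 1.0, 1.2, 1.5, 2.0)
  P <- rbind(
    c(0, 0, 0, 5, 0, 0), # point mass at 1.2
    c(0, 0, 2, 0, 0, 2), # equal mass at 1.0 and 2.0
    c(0, 3, 0, 0, 0, 1) # 3 at 0.0, 1 at 2.0
  )
  vm <- mean_envelope(make_spec(P, v))
  expect_equal(vm, c(1.2, 1.5, 0.5))
  expect_error(mean_envelope(make_spec(P * 0, v)), "all-zero")
  P2 <- rbind(P, 0)
  expect_true(is.na(mean_envelope(make_spec(P2, v))[4]))
})

test_that("significant peaks follow the local-maximum + relative-threshold rule", {
  g <- c(-2, -1, 0, 1, 2)
  pk <- significant_peaks(c(0.1, 1.0, 0.2, 0.3, 0.1), g, rho = 0.2)
  expect_equal(pk$velocity, c(-1, 1))
  expect_equal(pk$amplitude, c(1.0, 0.3))
  # second local maximum excluded: 0.18 <= 0.2 * 1.0
  pk2 <- significant_peaks(c(0.1, 1.0, 0.15, 0.18, 0.1), g, rho = 0.2)
  expect_equal(pk2$velocity, -1)
  # single interior nonzero bin
  pk3 <- significant_peaks(c(0, 0, 5, 0, 0), g, rho = 0.2)
  expect_equal(pk3$velocity, 0)
  # all-zero frame
  expect_equal(nrow(significant_peaks(rep(0, 5), g, rho = 0.2)), 0L)
  # plateau counts once, at its leftmost bin
  pk4 <- significant_peaks(c(0.1, 0.8, 0.8, 0.1, 0.3, 0.1, 0), seq(-3, 3), rho = 0.2)
  expect_equal(pk4$velocity, c(-2, 1))
  expect_error(significant_peaks(c(1, 2, 1), 1:3, rho = 1.2), "between 0 and 1")
  expect_error(significant_peaks(c(-1, 2, 1), 1:3, rho = 0.2), "non-negative")
})

test_that("raising the threshold never adds peaks", {
  set.seed(7)
  g <- seq(-2, 2, length.out = 41)
  for (k in 1:25) {
    a <- abs(rnorm(41)) * stats::filter(runif(41), rep(1, 3), circular = TRUE)
    a <- as.numeric(abs(a))
    counts <- vapply(
      c(0.05, 0.2, 0.5, 0.8),
      function(r) nrow(significant_peaks(a, g, rho = r)), integer(1)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a single constant-velocity scatterer pins all three envelopes", {
  v <- 1.0
  sp <- compute_spectrogram(constant_velocity_signal(v, duration = 1.5))
  env <- extract_envelopes(sp)
  bin <- velocity_resolution(sp)
  expect_true(all(abs(env$v_u - v) <= bin))
  expect_true(all(abs(env$v_l - v) <= bin))
  expect_true(all(abs(env$v_m - v) <= bin))
  argmax <- sp$velocities[apply(sp$power, 1L, which.max)]
  expect_true(all(abs(argmax - v) <= bin))
  # identical for any rho in (0,1): single-component spectra are threshold-free
  env2 <- extract_envelopes(sp, rho = 0.9)
  env3 <- extract_envelopes(sp, rho = 0.05)
  expect_equal(env$v_u, env2$v_u)
  expect_equal(env$v_l, env3$v_l)
})

test_that("no-peak frames carry the previous frame forward; an empty first frame errors", {
  v <- seq(-2, 2, length.out = 9)
  P <- rbind(
    c(0, 0, 0, 0, 4, 0, 0, 0, 0),
    rep(0, 9),
    c(0, 0, 4, 0, 0, 0, 4, 0, 0)
  )
  env <- suppressMessages(extract_envelopes(make_spec(P, v)))
  expect_equal(env$v_u[2], env$v_u[1])
  expect_equal(env$v_l[2], env$v_l[1])
  expect_equal(env$n_carried, 1L)
  expect_true(is.na(env$v_m[2]))
  expect_equal(env$v_u[3], 1)
  expect_equal(env$v_l[3], -1)
  Pbad <- P[c(2, 1, 3), ]
  expect_error(extract_envelopes(make_spec(Pbad, v)), "first frame")
})

test_that("condition channel sets match the fixed table", {
  expect_equal(condition_channels(1), "v_u")
  expect_equal(condition_channels(2), "v_m")
  expect_equal(condition_channels(3), "v_l")
  expect_equal(condition_channels(4), c("v_u", "v_m"))
  expect_equal(condition_channels(5), c("v_u", "v_l"))
  expect_equal(condition_channels(6), c("v_m", "v_l"))
  expect_equal(condition_channels(7), c("v_u", "v_m", "v_l"))
  expect_error(condition_channels(0), "between 1 and 7")
  expect_error(condition_channels(8), "between 1 and 7")
})

test_that("condition inputs stack the selected envelope series in order", {
  prep <- tiny_prepared()
  env <- prep$envelopes[[1]]
  m3 <- build_condition_input(env, 3)
  expect_equal(dim(m3), c(length(env$frame_times), 1L))
  expect_equal(unname(m3[, 1]), env$v_l)
  m7 <- build_condition_input(env, 7)
  expect_equal(colnames(m7), c("v_u", "v_m", "v_l"))
  expect_equal(unname(m7[, "v_m"]), env$v_m)
})

test_that("envelope sets round-trip through the columnar text format", {
  env <- tiny_prepared()$envelopes[[2]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_envelopes(env, path)
  back <- read_envelopes(path)
  expect_equal(back$v_u, env$v_u)
  expect_equal(back$v_m, env$v_m)
  expect_equal(back$v_l, env$v_l)
  expect_equal(back$rho, env$rho)
})
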