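test_that("parameter draws are deterministic under a fixed seed", {
  p1 <- sample_class_params("young", rng_seed = 1)
  p2 <- sample_class_params("young", rng_seed = 1)
  expect_identical(p1, p2)
  p3 <- sample_class_params("young", rng_seed = 2)
  expect_false(identical(p1$torso_speed, p3$torso_speed))
})

test_that("draws match the configured class distribution", {
  cfg <- gait_default_config()
  draws <- vapply(
    1:1000,
    function(k) sample_class_params("elderly", rng_seed = k)$torso_speed,
    numeric(1)
  )
  se <- cfg$elderly$torso_speed_sd / sqrt(1000)
  expect_lt(abs(mean(draws) - cfg$elderly$torso_speed_mean), 3 * se)
})

test_that("unknown class labels are rejected with the admissible set", {
  expect_error(sample_class_params("child", rng_seed = 1), "young, elderly")
})

test_that("zero articulation collapses to a rigid cluster at constant torso speed", {
  p <- sample_class_params("young", rng_seed = 1)
  p$swing_peak_velocity <- 0
  p$torso_fluct_amp <- 0
  traj <- simulate_walker(p, n_cycles = 2)
  expect_true(all(abs(traj$radial_velocities - p$torso_speed) < 1e-12))
})

test_that("foot tracks reach the drawn swing peak and mirror each other at half a cycle", {
  p <- sample_class_params("young", rng_seed = 4)
  traj <- simulate_walker(p, n_cycles = 4, config = radar_config())
  vr <- traj$radial_velocities[, "right_foot"]
  vl <- traj$radial_velocities[, "left_foot"]
  expect_lt(abs(max(vr) - p$swing_peak_velocity) / p$swing_peak_velocity, 0.05)
  shift <- round(p$cycle_duration / 2 * traj$fs)
  n <- length(vr)
  expect_equal(
    vl[(shift + 1):n], vr[1:(n - shift)],
    tolerance = 0.05
  )
})

test_that("radial velocity is the negative time-derivative of range", {
  p <- sample_class_params("elderly", rng_seed = 6)
  traj <- simulate_walker(p, n_cycles = 3, rng_seed = 9)
  fd <- -apply(traj$ranges, 2L, diff) * traj$fs
  mid <- (traj$radial_velocities[-1, ] + traj$radial_velocities[-nrow(traj$ranges), ]) / 2
  # trapezoidal integration makes the midpoint rule exact
  expect_equal(unname(fd), unname(mid), tolerance = 1e-9)
  expect_true(all(traj$ranges > 0))
  # walker approaches: every range decreases over the full walk
  expect_true(all(traj$ranges[nrow(traj$ranges), ] < traj$ranges[1, ]))
})

test_that("each foot is slow for at least 40% of the cycle under defaults", {
  for (lbl in c("young", "elderly")) {
    p <- sample_class_params(lbl, rng_seed = 11)
    traj <- simulate_walker(p, n_cycles = 4)
    frac <- mean(abs(traj$radial_velocities[, "right_foot"]) <=
      p$stance_residual_velocity + 1e-9)
    expect_gte(frac, 0.40)
  }
})

test_that("aliased kinematics are refused", {
  p <- sample_class_params("young", rng_seed = 1)
  p$swing_peak_velocity <- 2.6
  expect_error(simulate_walker(p, n_cycles = 2), "Nyquist")
  p2 <- sample_class_params("young", rng_seed = 1)
  expect_error(simulate_walker(p2, n_cycles = 4, start_range = 2), "range")
})

test_that("class configurations round-trip through the YAML config file", {
  cfg <- gait_default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gait_config(cfg, path)
  back <- read_gait_config(path)
  expect_equal(back$young$torso_speed_mean, cfg$young$torso_speed_mean)
  expect_equal(back$elderly$limb_reflectivities, cfg$elderly$limb_reflectivities)
  expect_s3_class(back$young, "gait_class_config")
})

test_that("cohort generation is deterministic, labeled, and sized as requested", {
  ds <- make_dataset(3, 4, rng_seed = 21)
  expect_equal(nrow(ds), 7L)
  expect_equal(as.integer(table(ds$label)[c("young", "elderly")]), c(3L, 4L))
  expect_equal(nrow(make_dataset(0, 0, rng_seed = 1)), 0L)
  ds2 <- make_dataset(3, 4, rng_seed = 21)
  expect_identical(ds$seed, ds2$seed)
  expect_identical(ds$signal[[5]]$samples, ds2$signal[[5]]$samples)
  expect_identical(ds$torso_speed, ds2$torso_speed)
})

test_that("the manifest records draws and seeds and round-trips", {
  ds <- make_dataset(2, 2, rng_seed = 33)
  dir <- withr::local_tempdir()
  path <- write_manifest(ds, dir, write_signals = TRUE)
  m <- read_manifest(path)
  expect_equal(nrow(m), 4L)
  expect_true(all(c("id", "label", "seed", "torso_speed", "signal_path") %in% names(m)))
  sig <- read_baseband(file.path(dir, m$signal_path[1]))
  expect_equal(sig$samples, ds$signal[[1]]$samples, tolerance = 1e-10)
})
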