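# Small separable sequence sets for fast classifier checks: class "young"
# oscillates around a higher level than "elderly".
toy_sequences <- function(n_per_class, t_len = 40, gap = 0.4, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(level, id) {
      tt <- seq_len(t_len + sample.int(10L, 1L)) # variable lengths
      matrix(level + 0.2 * sin(tt / 3) + rnorm(length(tt), sd = sd),
        ncol = 1, dimnames = list(NULL, "v_l")
      )
    }
    tibble::tibble(
      id = sprintf("t%02d", seq_len(2 * n_per_class)),
      label = rep(c("young", "elderly"), each = n_per_class),
      sequence = c(
        lapply(seq_len(n_per_class), function(i) mk(1.0 + gap, i)),
        lapply(seq_len(n_per_class), function(i) mk(1.0, i))
      )
    )
  })
}

fast_cfg <- function(...) {
  lstm_config_test_scale(hidden_units = 16, batch_size = 16, max_epochs = 25, ...)
}

test_that("training input contracts are enforced", {
  toy <- toy_sequences(4)
  one_class <- toy[toy$label == "young", ]
  expect_error(train_lstm(one_class, fast_cfg()), "single-class")
  mixed <- toy
  mixed$sequence[[1]] <- cbind(mixed$sequence[[1]], mixed$sequence[[1]])
  expect_error(train_lstm(mixed, fast_cfg()), "channel")
  expect_error(train_lstm(toy[1, ], fast_cfg()), "at least 2")
})

test_that("training is reproducible and its loss decreases on separable data", {
  toy <- toy_sequences(8)
  f1 <- train_lstm(toy, fast_cfg(rng_seed = 5))
  f2 <- train_lstm(toy, fast_cfg(rng_seed = 5))
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$params, f2$params)
  # loss decreases over the first decay period
  expect_lt(f1$log$loss[25], f1$log$loss[1])
  # learning-rate schedule: constant within the first decay period
  expect_equal(unique(f1$log$lr), fast_cfg()$initial_lr)
  f3 <- train_lstm(toy, lstm_config_test_scale(
    hidden_units = 16, batch_size = 16, rng_seed = 5, max_epochs = 61
  ))
  expect_equal(f3$log$lr[61], f3$log$lr[1] * 0.9^2)
})

test_that("a converged model separates the toy classes and emits proper probabilities", {
  toy <- toy_sequences(10)
  fit <- train_lstm(toy, fast_cfg(rng_seed = 2))
  pred <- predict(fit, toy)
  expect_gte(mean(pred$.pred_label == toy$label), 0.95)
  expect_true(all(abs(pred$.pred_young + pred$.pred_elderly - 1) < 1e-6))
  expect_true(all(pred$.pred_young >= 0 & pred$.pred_elderly >= 0))
})

test_that("prediction is per-sequence: independent of companions in the batch", {
  toy <- toy_sequences(6)
  fit <- train_lstm(toy, fast_cfg(rng_seed = 7))
  alone <- predict(fit, toy$sequence[[3]])
  together <- predict(fit, toy)
  expect_equal(alone$.pred_young, together$.pred_young[3])
})

test_that("prediction guards channel counts and sequence length", {
  toy <- toy_sequences(4)
  fit <- train_lstm(toy, fast_cfg(rng_seed = 1))
  expect_error(predict(fit, matrix(1, 5, 2)), "channel")
  expect_error(predict(fit, matrix(numeric(0), 0, 1)), "zero-length")
})

test_that("velocity parameters reduce envelopes to the fixed 12-feature vector", {
  env <- structure(
    list(
      frame_times = 0:2 / 75,
      v_u = c(1, 1, 1), v_m = c(1, 1, 1), v_l = c(0, 1, 2),
      rho = 0.2, n_carried = 0L, source = "test"
    ),
    class = "envelope_set"
  )
  f <- velocity_parameters(env)
  expect_named(f, c(
    "vu_mean", "vu_sd", "vu_max", "vu_min",
    "vm_mean", "vm_sd", "vm_max", "vm_min",
    "vl_mean", "vl_sd", "vl_max", "vl_min"
  ))
  expect_equal(unname(f[c("vu_mean", "vu_sd", "vu_max", "vu_min")]), c(1, 0, 1, 1))
  # population sd convention
  expect_equal(unname(f["vl_sd"]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(f["vl_mean"]), 1)
  expect_equal(unname(f[c("vl_max", "vl_min")]), c(2, 0))
  env$v_m[2] <- NA_real_
  expect_error(velocity_parameters(env), "undefined")
  env$frame_times <- numeric(0)
  expect_error(velocity_parameters(env), "empty")
})

test_that("the SVM baseline fits separable features and guards degenerate input", {
  set.seed(31)
  X <- data.frame(
    a = c(rnorm(20, 0), rnorm(20, 4)),
    b = c(rnorm(20, 0), rnorm(20, 4)),
    flat = 1
  )
  labels <- rep(c("young", "elderly"), each = 20)
  expect_warning(fit <- train_svm_baseline(X, labels, rng_seed = 1), "zero-variance")
  expect_equal(fit$features, c("a", "b"))
  pred <- predict(fit, X)
  expect_equal(mean(pred$.pred_label == labels), 1.0)
  expect_error(
    train_svm_baseline(X[1:20, ], labels[1:20], rng_seed = 1),
    "per class"
  )
  expect_error(predict(fit, X["a"]), "lacks feature")
})
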