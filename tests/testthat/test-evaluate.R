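test_that("the 7:3 hold-out split reproduces the cohort arithmetic", {
  ds <- tibble::tibble(label = rep(c("young", "elderly"), c(87, 213)))
  sp <- holdout_split(ds, rng_seed = 1)
  expect_equal(nrow(sp$train), 210L)
  expect_equal(nrow(sp$test), 90L)
  # stratified class allocation
  expect_equal(sum(sp$train$label == "young"), 61L)
  expect_equal(sum(sp$train$label == "elderly"), 149L)
})

test_that("splits partition the data exactly", {
  ds <- tibble::tibble(
    id = 1:10,
    label = rep(c("young", "elderly"), 5)
  )
  sp <- holdout_split(ds, rng_seed = 3)
  expect_equal(nrow(sp$train), 7L)
  expect_equal(nrow(sp$test), 3L)
  expect_setequal(c(sp$train$id, sp$test$id), ds$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_error(holdout_split(ds, ratio = 1.2), "between 0 and 1")
  expect_error(holdout_split(ds[1, , drop = FALSE]), "at least 2")
  # reproducible under the seed
  sp2 <- holdout_split(ds, rng_seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
})

test_that("single-trial reports collapse to that trial and confusion rows sum to 100", {
  prep <- tiny_prepared()
  ev <- evaluate_condition(prep, "svm", n_trials = 1, master_seed = 5)
  expect_equal(ev$mean_accuracy, ev$per_trial$accuracy[1])
  expect_equal(unname(rowSums(ev$confusion)), c(100, 100), tolerance = 0.1)
  expect_equal(ev$n_trials, 1L)
})

test_that("mean accuracy equals the pooled-count accuracy when test sizes are equal", {
  prep <- tiny_prepared()
  ev <- evaluate_condition(prep, "svm", n_trials = 4, master_seed = 11)
  expect_equal(length(unique(ev$per_trial$n_test)), 1L)
  pooled <- sum(diag(ev$confusion_counts)) / sum(ev$confusion_counts)
  expect_equal(ev$mean_accuracy, pooled)
  expect_identical(ev$seeds, ev$per_trial$seed)
})

test_that("conditions evaluated under one master seed share identical trial splits", {
  prep <- tiny_prepared()
  cfg <- lstm_config_test_scale(hidden_units = 8, max_epochs = 3)
  cmp <- compare_conditions(prep, c("2", "3"),
    n_trials = 2, config = cfg,
    master_seed = 9
  )
  expect_equal(nrow(cmp), 2L)
  r2 <- cmp$report[[1]]
  r3 <- cmp$report[[2]]
  expect_identical(r2$per_trial$seed, r3$per_trial$seed)
  for (k in seq_len(2)) {
    expect_identical(r2$per_trial$test_ids[[k]], r3$per_trial$test_ids[[k]])
  }
})

test_that("reports are reproducible and persist as structured text", {
  prep <- tiny_prepared()
  ev1 <- evaluate_condition(prep, "svm", n_trials = 2, master_seed = 21)
  ev2 <- evaluate_condition(prep, "svm", n_trials = 2, master_seed = 21)
  expect_identical(ev1$per_trial$accuracy, ev2$per_trial$accuracy)
  expect_identical(ev1$confusion, ev2$confusion)
  dir <- withr::local_tempdir()
  write_eval_report(ev1, dir)
  per_trial <- readr::read_csv(file.path(dir, "per_trial.csv"), show_col_types = FALSE)
  expect_equal(per_trial$accuracy, ev1$per_trial$accuracy)
  conf <- readr::read_csv(file.path(dir, "confusion.csv"), show_col_types = FALSE)
  expect_equal(nrow(conf), 4L)
})

test_that("evaluation rejects an empty dataset", {
  empty <- tibble::tibble(label = factor(), envelopes = list())
  expect_error(evaluate_condition(empty, 3, n_trials = 1), "empty")
})
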