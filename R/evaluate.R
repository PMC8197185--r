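#' Random hold-out split of a labeled dataset
#'
#' Disjoint, exhaustive train/test partition. The training set has exactly
#' `round(ratio * n)` rows; with `stratified = TRUE` (default) the per-class
#' training counts are allocated by largest remainder so class proportions
#' are preserved as closely as integer counts allow (a 300-row cohort of
#' 87/213 at ratio 0.7 gives 61 + 149 = 210 training and 90 test rows).
#'
#' @param data A data frame with a `label` column.
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.7,
#'   i.e. a 7:3 split).
#' @param stratified Preserve class proportions in both parts (default TRUE).
#' @param rng_seed Integer seed.
#' @return List with elements `train` and `test`.
#' @examples
#' ds <- tibble::tibble(label = rep(c("young", "elderly"), c(87, 213)))
#' sp <- holdout_split(ds, rng_seed = 1)
#' nrow(sp$train); nrow(sp$test) # 210, 90
#' @export
holdout_split <- function(data, ratio = 0.7, stratified = TRUE, rng_seed = 1) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(data)
  if (n < 2L) stop("dataset must have at least 2 rows", call. = FALSE)
  n_train <- round(ratio * n)
  idx_train <- with_seed(rng_seed, {
    if (stratified) {
      labels <- as.character(data$label)
      classes <- unique(labels)
      quota <- ratio * table(labels)[classes]
      base <- floor(quota)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        fewer <- order(quota - base)[seq_len(-rem)]
        base[fewer] <- base[fewer] - 1
      }
      unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        sample(idx, base[[cl]])
      }), use.names = FALSE)
    } else {
      sample.int(n, n_train)
    }
  })
  list(
    train = data[sort(idx_train), , drop = FALSE],
    test = data[setdiff(seq_len(n), idx_train), , drop = FALSE]
  )
}

#' Repeated hold-out evaluation of one input condition
#'
#' Runs `n_trials` independent 7:3 hold-out trials: each trial draws its own
#' stratified split with a seed derived from `master_seed`, trains a fresh
#' classifier on the training part and scores the held-out part. Accuracies
#' are averaged over trials and predictions pooled into a confusion matrix.
#' Conditions 1-7 train the LSTM on the corresponding envelope channels;
#' condition `"svm"` trains the velocity-parameter SVM baseline instead.
#'
#' @param prepared A tibble from [prepare_sequences()] (columns `label` and
#'   `envelopes`).
#' @param condition Integer 1..7, or `"svm"` for the baseline.
#' @param n_trials Number of hold-out trials (default 30).
#' @param config An [lstm_config()] (ignored for `"svm"`).
#' @param master_seed Master seed; trial k uses the derived seed
#'   `derive_seed(master_seed, k)` for its split and training, so reports are
#'   reproducible and different conditions evaluated under the same
#'   `master_seed` share identical trial splits (paired comparison).
#' @param ratio Training fraction (default 0.7).
#'
#' @return An object of class `gait_eval`: `condition`, `per_trial` (tibble
#'   with trial, seed, accuracy, n_train, n_test), `mean_accuracy`,
#'   `confusion` (2x2 row-normalized percentages, rows = predicted class,
#'   columns = true class), `confusion_counts`, `n_trials`, `split_ratio`,
#'   `seeds`. Methods: `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' \donttest{
#' ds <- prepare_sequences(make_dataset(10, 10, rng_seed = 1))
#' ev <- evaluate_condition(ds, 3,
#'   n_trials = 2,
#'   config = lstm_config_test_scale(max_epochs = 10)
#' )
#' glance(ev)
#' }
#' @export
evaluate_condition <- function(prepared, condition, n_trials = 30,
                               config = lstm_config(), master_seed = 1,
                               ratio = 0.7) {
  stopifnot(is.data.frame(prepared), all(c("label", "envelopes") %in% names(prepared)))
  if (nrow(prepared) == 0L) stop("dataset is empty", call. = FALSE)
  is_svm <- identical(condition, "svm") || identical(condition, "svm_baseline")
  if (!is_svm) condition_channels(condition) # validates 1..7

  data <- if (is_svm) {
    velocity_parameter_table(prepared)
  } else {
    condition_sequences(prepared, condition)
  }
  if (!"id" %in% names(data)) data$id <- sprintf("row_%03d", seq_len(nrow(data)))

  lv <- gait_labels()
  counts <- matrix(0, 2, 2, dimnames = list(predicted = lv, true = lv))
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    seed_k <- derive_seed(master_seed, k)
    sp <- holdout_split(data, ratio = ratio, stratified = TRUE, rng_seed = seed_k)
    if (is_svm) {
      fit <- train_svm_baseline(sp$train, rng_seed = seed_k)
      pred <- predict(fit, sp$test)$.pred_label
    } else {
      cfg <- config
      cfg$rng_seed <- derive_seed(seed_k, 1L)
      fit <- train_lstm(sp$train, cfg)
      pred <- predict(fit, sp$test)$.pred_label
    }
    truth <- factor(as.character(sp$test$label), levels = lv)
    counts <- counts + table(
      factor(pred, levels = lv),
      truth
    )
    rows[[k]] <- tibble::tibble(
      trial = k, seed = seed_k,
      accuracy = mean(pred == truth),
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      test_ids = list(sp$test$id)
    )
  }
  per_trial <- dplyr::bind_rows(rows)
  row_tot <- rowSums(counts)
  confusion <- 100 * counts / ifelse(row_tot == 0, 1, row_tot)
  structure(
    list(
      condition = condition,
      per_trial = per_trial,
      mean_accuracy = mean(per_trial$accuracy),
      confusion = confusion,
      confusion_counts = counts,
      n_trials = n_trials,
      split_ratio = c(train = ratio, test = 1 - ratio),
      seeds = per_trial$seed
    ),
    class = "gait_eval"
  )
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf(
    "<gait_eval> condition %s: mean accuracy %.3f over %d trial(s) (split %.0f:%.0f)\n",
    as.character(x$condition), x$mean_accuracy, x$n_trials,
    100 * x$split_ratio["train"], 100 * x$split_ratio["test"]
  ))
  cat("confusion (% within predicted class; rows = predicted, cols = true):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' @describeIn evaluate_condition Per-trial accuracies as a tibble.
#' @param x A `gait_eval`.
#' @param ... Unused.
#' @method tidy gait_eval
#' @export
tidy.gait_eval <- function(x, ...) {
  dplyr::mutate(x$per_trial, condition = as.character(x$condition), .before = 1L)
}

#' @describeIn evaluate_condition One-row summary (mean accuracy, trial
#'   count, per-class recall-style confusion diagonal).
#' @method glance gait_eval
#' @export
glance.gait_eval <- function(x, ...) {
  tibble::tibble(
    condition = as.character(x$condition),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$per_trial$accuracy),
    n_trials = x$n_trials,
    pct_young_correct = x$confusion["young", "young"],
    pct_elderly_correct = x$confusion["elderly", "elderly"]
  )
}

#' @describeIn evaluate_condition Box plot of per-trial accuracies.
#' @param object A `gait_eval`.
#' @method autoplot gait_eval
#' @export
autoplot.gait_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.5) +
    ggplot2::labs(x = "input condition", y = "hold-out accuracy") +
    ggplot2::theme_minimal()
}

#' Compare input conditions under paired hold-out trials
#'
#' Evaluates each requested condition with [evaluate_condition()] under the
#' same `master_seed`, so every condition sees identical trial splits
#' (paired comparison, which sharpens between-condition contrasts).
#'
#' @inheritParams evaluate_condition
#' @param conditions Vector of conditions: integers in 1..7 and/or `"svm"`.
#' @return A tibble with one row per condition: `condition`,
#'   `mean_accuracy`, `sd_accuracy`, per-class correct percentages, and the
#'   full `gait_eval` in list-column `report`.
#' @export
compare_conditions <- function(prepared, conditions = c(1:7, "svm"),
                               n_trials = 30, config = lstm_config(),
                               master_seed = 1, ratio = 0.7) {
  reports <- lapply(conditions, function(cond) {
    cond2 <- if (cond %in% as.character(1:7)) as.integer(cond) else cond
    evaluate_condition(prepared, cond2,
      n_trials = n_trials, config = config,
      master_seed = master_seed, ratio = ratio
    )
  })
  out <- purrr::map_dfr(reports, glance)
  out$report <- reports
  out
}

#' Persist an evaluation report as structured text
#'
#' Writes `per_trial.csv` (trial, seed, accuracy, split sizes and the
#' held-out ids, so any table cell can be re-derived) and `confusion.csv`
#' (row-normalized percentages) into `dir`.
#'
#' @param report A `gait_eval`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "gait_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per_trial <- report$per_trial
  per_trial$test_ids <- vapply(per_trial$test_ids, paste, character(1), collapse = ";")
  readr::write_csv(per_trial, file.path(dir, "per_trial.csv"))
  conf <- tibble::as_tibble(as.data.frame(report$confusion))
  names(conf) <- c("predicted", "true", "percent")
  readr::write_csv(conf, file.path(dir, "confusion.csv"))
  invisible(dir)
}
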