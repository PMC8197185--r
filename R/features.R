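#' Summary velocity parameters of an envelope set
#'
#' The feature vector of the parameter-based baseline classifier: mean,
#' standard deviation, maximum and minimum of each of the three envelope
#' series, in the fixed order `v_u`, `v_m`, `v_l` — twelve features in total.
#' The standard deviation uses the population convention (divide by n) so the
#' features are exactly reproducible. This concrete twelve-feature set is
#' this package's stand-in for "simple parameters such as mean and standard
#' deviation" of earlier velocity-parameter classifiers; the original
#' parameter list is not enumerated anywhere and should not be assumed to
#' coincide with this one.
#'
#' @param env An `envelope_set` from [extract_envelopes()].
#' @return Named numeric vector of length 12
#'   (`vu_mean, vu_sd, vu_max, vu_min, vm_..., vl_...`).
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' sp <- compute_spectrogram(synthesize_baseband(simulate_walker(p, 3)))
#' velocity_parameters(extract_envelopes(sp))
#' @export
velocity_parameters <- function(env) {
  stopifnot(inherits(env, "envelope_set"))
  if (length(env$frame_times) == 0L) stop("empty envelope set", call. = FALSE)
  series <- list(vu = env$v_u, vm = env$v_m, vl = env$v_l)
  if (any(vapply(series, function(s) any(is.na(s)), logical(1)))) {
    stop("envelope set contains undefined frames", call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- unlist(lapply(series, function(s) {
    c(mean = mean(s), sd = pop_sd(s), max = max(s), min = min(s))
  }))
  names(out) <- sub("\\.", "_", names(out))
  out
}

#' Velocity-parameter feature table for a prepared dataset
#'
#' @param prepared A tibble from [prepare_sequences()].
#' @return A tibble with `id`, `label` and the 12 feature columns; the
#'   columnar-text interchange format of the baseline stage
#'   (write with [readr::write_csv()]).
#' @export
velocity_parameter_table <- function(prepared) {
  stopifnot(is.data.frame(prepared), "envelopes" %in% names(prepared))
  feats <- purrr::map_dfr(prepared$envelopes, function(e) {
    tibble::as_tibble(as.list(velocity_parameters(e)))
  })
  dplyr::bind_cols(dplyr::select(
    prepared,
    dplyr::any_of(c("id", "label"))
  ), feats)
}

#' Train the SVM baseline on velocity parameters
#'
#' Radial-basis-function support vector machine on the twelve summary
#' velocity parameters, the earlier-generation baseline against which the
#' sequence classifier is compared. Features are standardized with
#' training-set mean/sd; `cost` and `gamma` are chosen by an internal
#' cross-validated grid search (logged in the returned object).
#' Zero-variance features are dropped with a warning.
#'
#' @param features A data frame of numeric features (non-feature columns
#'   `id`/`label` are ignored), e.g. from [velocity_parameter_table()].
#' @param labels Factor or character vector of `"young"`/`"elderly"` labels
#'   (defaults to `features$label`).
#' @param rng_seed Integer seed for the cross-validation folds.
#' @param cost_grid,gamma_grid Hyper-parameter grids.
#' @return An object of class `gait_svm`: the fitted `e1071::svm` model, the
#'   retained feature names, label levels and the grid-search log.
#' @export
train_svm_baseline <- function(features, labels = NULL, rng_seed = 1,
                               cost_grid = 10^(-1:2),
                               gamma_grid = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(features)) stop("`labels` missing and no `label` column", call. = FALSE)
    labels <- features$label
  }
  labels <- factor(as.character(labels), levels = gait_labels())
  if (any(is.na(labels))) stop("labels must be 'young' or 'elderly'", call. = FALSE)
  X <- as.data.frame(features)[, setdiff(names(features), c("id", "label")), drop = FALSE]
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (min(table(labels)) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  zero_var <- vapply(X, function(col) stats::sd(col) == 0, logical(1))
  if (any(zero_var)) {
    warning(sprintf(
      "dropping zero-variance feature(s): %s",
      paste(names(X)[zero_var], collapse = ", ")
    ), call. = FALSE)
    X <- X[, !zero_var, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no usable features remain", call. = FALSE)
  if (is.null(gamma_grid)) gamma_grid <- c(0.25, 1, 4) / ncol(X)

  # standardize with training-set mean/sd (a fold-constant feature gets unit
  # scale: it carries no information but must not derail the kernel)
  center <- vapply(X, mean, numeric(1))
  scale_ <- vapply(X, stats::sd, numeric(1))
  scale_[scale_ < 1e-12] <- 1
  Xs <- as.data.frame(scale(X, center = center, scale = scale_))

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  k <- min(5L, min(table(labels)))
  cv_acc <- with_seed(rng_seed, {
    folds <- make_stratified_folds(labels, k)
    vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- e1071::svm(
          x = Xs[tr, , drop = FALSE], y = labels[tr],
          kernel = "radial", cost = grid$cost[g], gamma = grid$gamma[g],
          scale = FALSE
        )
        mean(stats::predict(fit, Xs[!tr, , drop = FALSE]) == labels[!tr])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
  })
  best <- which.max(cv_acc)
  model <- e1071::svm(
    x = Xs, y = labels, kernel = "radial",
    cost = grid$cost[best], gamma = grid$gamma[best], scale = FALSE
  )
  structure(
    list(
      model = model,
      features = names(X),
      center = center,
      scale = scale_,
      levels = gait_labels(),
      grid = dplyr::bind_cols(tibble::as_tibble(grid), cv_accuracy = cv_acc),
      best = grid[best, ]
    ),
    class = "gait_svm"
  )
}

make_stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf(
    "<gait_svm> RBF kernel, %d features, cost = %g, gamma = %g (CV accuracy %.3f)\n",
    length(x$features), x$best$cost, x$best$gamma,
    max(x$grid$cv_accuracy)
  ))
  invisible(x)
}

#' Predict gait class with the SVM baseline
#'
#' @param object A `gait_svm` from [train_svm_baseline()].
#' @param new_data Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return A tibble with column `.pred_label`.
#' @export
predict.gait_svm <- function(object, new_data, ...) {
  missing <- setdiff(object$features, names(new_data))
  if (length(missing)) {
    stop(sprintf("new data lacks feature(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- as.data.frame(new_data)[, object$features, drop = FALSE]
  X <- as.data.frame(scale(X, center = object$center, scale = object$scale))
  pred <- stats::predict(object$model, X)
  tibble::tibble(.pred_label = factor(as.character(pred), levels = object$levels))
}

#' @describeIn train_svm_baseline Grid-search log as a tibble.
#' @param x A `gait_svm`.
#' @param ... Unused.
#' @method tidy gait_svm
#' @export
tidy.gait_svm <- function(x, ...) x$grid
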