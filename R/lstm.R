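#' LSTM training configuration
#'
#' Hyper-parameters of the sequence-to-label LSTM classifier. The defaults
#' are the full-scale settings — 400 hidden cells, batch size 128, initial
#' learning rate 1e-4, attenuated by 0.9 every 30 epochs under Adam — with a
#' 150-epoch budget and no early stopping, so the decay schedule executes
#' meaningfully.
#'
#' @param hidden_units Number of LSTM hidden cells.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_decay Multiplicative learning-rate attenuation factor.
#' @param decay_every Epoch interval between attenuations.
#' @param max_epochs Training epochs.
#' @param rng_seed Integer seed for initialization and batch shuffling.
#' @param masking If `TRUE`, the class read-out uses each sequence's true
#'   final frame; if `FALSE` (default) the read-out is the final frame of the
#'   zero-padded batch, i.e. plain zero-padding without masking.
#' @param standardize If `TRUE`, channels are standardized with training-set
#'   mean/sd; default `FALSE` (raw velocities in m/s).
#' @param class_weights If `TRUE`, cross-entropy terms are weighted inversely
#'   to class frequency; default `FALSE` (plain cross-entropy).
#' @param clip_norm Global gradient-norm clip; `Inf` disables.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 400, batch_size = 128,
                        initial_lr = 1e-4, lr_decay = 0.9, decay_every = 30,
                        max_epochs = 150, rng_seed = 1,
                        masking = FALSE, standardize = FALSE,
                        class_weights = FALSE, clip_norm = 5) {
  stopifnot(
    hidden_units > 0, batch_size >= 1,
    initial_lr > 0, lr_decay > 0, lr_decay <= 1,
    decay_every >= 1, max_epochs >= 1, clip_norm > 0
  )
  structure(
    list(
      hidden_units = as.integer(hidden_units),
      batch_size = as.integer(batch_size),
      initial_lr = initial_lr, lr_decay = lr_decay,
      decay_every = as.integer(decay_every),
      max_epochs = as.integer(max_epochs),
      rng_seed = as.integer(rng_seed),
      masking = isTRUE(masking), standardize = isTRUE(standardize),
      class_weights = isTRUE(class_weights), clip_norm = clip_norm
    ),
    class = "lstm_config"
  )
}

#' Reduced-scale LSTM configuration
#'
#' A smaller network (64 hidden cells, batch 32, learning rate 1e-3, 40
#' epochs, channel standardization on) whose optimization is sized for
#' desk-scale simulated cohorts of a few hundred short sequences; used
#' throughout the package's tests, examples and reproduction script.
#' Standardization matters at this scale because the lower envelope lives on
#' a ~0.05 m/s scale and a small network given few hundred updates cannot
#' rescale it internally; the full-scale configuration keeps raw velocities.
#' Architecture and schedule shape (Adam, 0.9 attenuation every 30 epochs,
#' zero-padding without masking) are unchanged from [lstm_config()].
#'
#' @param ... Overrides passed to [lstm_config()].
#' @return An `lstm_config`.
#' @export
lstm_config_test_scale <- function(...) {
  args <- list(...)
  defaults <- list(
    hidden_units = 64, batch_size = 32, initial_lr = 1e-3,
    max_epochs = 40, standardize = TRUE
  )
  do.call(lstm_config, utils::modifyList(defaults, args))
}

# --- parameter initialization -----------------------------------------------

# Gate row blocks in W/U/b: [input; forget; output; candidate].
init_lstm_params <- function(n_channels, H) {
  glorot <- function(nr, nc, fan_in, fan_out) {
    l <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -l, l), nr, nc)
  }
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1 # forget-gate bias opens the memory path at init
  list(
    W = glorot(4 * H, n_channels, n_channels, H),
    U = glorot(4 * H, H, H, H),
    b = b,
    Wout = glorot(2, H, H, 2),
    bout = numeric(2)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- forward / backward over one zero-padded batch --------------------------
# A: C x B x Tmax array of (possibly zero-padded) input frames
# lens: true sequence lengths; Y: 2 x B one-hot labels; wts: per-sample loss
# weights summing to B. Returns loss, class probabilities and gradients.
lstm_loss_grads <- function(par, A, lens, Y, masking, wts, want_grads = TRUE) {
  H <- ncol(par$U)
  C <- ncol(par$W)
  B <- dim(A)[2]
  Tmax <- dim(A)[3]
  i1 <- 1:H
  i2 <- (H + 1):(2 * H)
  i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)

  Hs <- vector("list", Tmax + 1L)
  Cs <- vector("list", Tmax + 1L)
  Hs[[1]] <- Cs[[1]] <- matrix(0, H, B)
  Ig <- Fg <- Og <- Gg <- Tc <- vector("list", Tmax)

  for (t in seq_len(Tmax)) {
    Xt <- matrix(A[, , t], nrow = C, ncol = B)
    Z <- par$W %*% Xt + par$U %*% Hs[[t]] + par$b
    i <- sigmoid(Z[i1, , drop = FALSE])
    f <- sigmoid(Z[i2, , drop = FALSE])
    o <- sigmoid(Z[i3, , drop = FALSE])
    g <- tanh(Z[i4, , drop = FALSE])
    cc <- f * Cs[[t]] + i * g
    tc <- tanh(cc)
    Hs[[t + 1L]] <- o * tc
    Cs[[t + 1L]] <- cc
    Ig[[t]] <- i
    Fg[[t]] <- f
    Og[[t]] <- o
    Gg[[t]] <- g
    Tc[[t]] <- tc
  }

  Hout <- if (masking) {
    vapply(seq_len(B), function(b) Hs[[lens[b] + 1L]][, b], numeric(H))
  } else {
    Hs[[Tmax + 1L]]
  }
  Hout <- matrix(Hout, nrow = H, ncol = B)

  logits <- par$Wout %*% Hout + par$bout
  logits <- sweep(logits, 2L, apply(logits, 2L, max))
  expl <- exp(logits)
  probs <- sweep(expl, 2L, colSums(expl), `/`)
  eps <- 1e-12
  loss <- -sum(wts * log(pmax(colSums(probs * Y), eps))) / B
  if (!want_grads) {
    return(list(loss = loss, probs = probs))
  }

  dLogits <- sweep(probs - Y, 2L, wts / B, `*`)
  grads <- list(
    W = matrix(0, 4 * H, C), U = matrix(0, 4 * H, H), b = numeric(4 * H),
    Wout = dLogits %*% t(Hout), bout = rowSums(dLogits)
  )
  dHout <- t(par$Wout) %*% dLogits

  dh <- matrix(0, H, B)
  dc <- matrix(0, H, B)
  if (!masking) dh <- dh + dHout
  for (t in Tmax:1L) {
    if (masking) {
      at_end <- which(lens == t)
      if (length(at_end)) dh[, at_end] <- dh[, at_end] + dHout[, at_end]
    }
    tc <- Tc[[t]]
    o <- Og[[t]]
    do <- dh * tc
    dcf <- dh * o * (1 - tc^2) + dc
    i <- Ig[[t]]
    f <- Fg[[t]]
    g <- Gg[[t]]
    di <- dcf * g
    df <- dcf * Cs[[t]]
    dg <- dcf * i
    dc <- dcf * f
    dZ <- rbind(
      di * i * (1 - i),
      df * f * (1 - f),
      do * o * (1 - o),
      dg * (1 - g^2)
    )
    Xt <- matrix(A[, , t], nrow = C, ncol = B)
    grads$W <- grads$W + dZ %*% t(Xt)
    grads$U <- grads$U + dZ %*% t(Hs[[t]])
    grads$b <- grads$b + rowSums(dZ)
    dh <- t(par$U) %*% dZ
  }
  list(loss = loss, probs = probs, grads = grads)
}

clip_global_norm <- function(grads, clip) {
  if (!is.finite(clip)) {
    return(grads)
  }
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# Stack a list of C x T matrices into a zero-padded C x B x Tmax array.
pad_batch <- function(seqs_t) {
  C <- nrow(seqs_t[[1]])
  lens <- vapply(seqs_t, ncol, integer(1))
  Tmax <- max(lens)
  A <- array(0, dim = c(C, length(seqs_t), Tmax))
  for (b in seq_along(seqs_t)) A[, b, seq_len(lens[b])] <- seqs_t[[b]]
  list(A = A, lens = lens)
}

#' Train the sequence-to-label LSTM gait classifier
#'
#' Architecture: sequence input (1-3 velocity channels) -> LSTM layer ->
#' fully connected layer -> softmax over the two classes (young, elderly).
#' Variable-length sequences are zero-padded to the maximum length within
#' each mini-batch (no masking by default); the loss is cross-entropy and the
#' optimizer Adam with a stepwise-attenuated learning rate.
#'
#' @param data A data frame with list-column `sequence` (frames x channels
#'   numeric matrices, as from [condition_sequences()]) and column `label`
#'   (values `"young"`/`"elderly"`); at least two sequences with both labels
#'   present and a common channel count.
#' @param config An [lstm_config()].
#' @return An object of class `gait_lstm`: learned parameters, the config
#'   snapshot, channel names, label levels, channel standardization stats (if
#'   enabled) and a per-epoch training log. Methods: [predict.gait_lstm()],
#'   `tidy()` (training log), `glance()`.
#' @examples
#' ds <- make_dataset(6, 6, rng_seed = 1)
#' seqs <- condition_sequences(prepare_sequences(ds), condition = 3)
#' fit <- train_lstm(seqs, lstm_config_test_scale(max_epochs = 2, rng_seed = 1))
#' tidy(fit)
#' @export
train_lstm <- function(data, config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"))
  stopifnot(is.data.frame(data), all(c("sequence", "label") %in% names(data)))
  seqs <- data$sequence
  labels <- factor(as.character(data$label), levels = gait_labels())
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 training sequences", call. = FALSE)
  if (any(is.na(labels))) stop("labels must be 'young' or 'elderly'", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("single-class training set: both labels must be present", call. = FALSE)
  }
  chans <- vapply(seqs, ncol, integer(1))
  if (length(unique(chans)) != 1L) {
    stop("mixed channel counts across sequences", call. = FALSE)
  }
  if (any(vapply(seqs, nrow, integer(1)) < 1L)) {
    stop("all sequences must have length >= 1", call. = FALSE)
  }
  C <- chans[1]
  channel_names <- colnames(seqs[[1]]) %||% paste0("ch", seq_len(C))

  std <- NULL
  if (config$standardize) {
    all_frames <- do.call(rbind, seqs)
    std <- list(mean = colMeans(all_frames), sd = apply(all_frames, 2L, stats::sd))
    std$sd[std$sd == 0] <- 1
    seqs <- lapply(seqs, function(s) sweep(sweep(s, 2L, std$mean), 2L, std$sd, `/`))
  }
  seqs_t <- lapply(seqs, t) # C x T for fast column access

  wts_by_class <- c(young = 1, elderly = 1)
  if (config$class_weights) {
    freq <- table(labels) / n
    wts_by_class <- c(young = 1, elderly = 1) / as.numeric(freq[gait_labels()])
    wts_by_class <- wts_by_class / mean(wts_by_class[as.integer(labels)])
  }

  Yall <- rbind(
    young = as.numeric(labels == "young"),
    elderly = as.numeric(labels == "elderly")
  )

  H <- config$hidden_units
  log_rows <- vector("list", config$max_epochs)

  fit <- with_seed(config$rng_seed, {
    par <- init_lstm_params(C, H)
    zeros <- lapply(par, function(p) p * 0)
    state <- list(t = 0L, m = zeros, v = zeros)

    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$initial_lr *
        config$lr_decay^((epoch - 1L) %/% config$decay_every)
      perm <- sample.int(n)
      batch_ids <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      losses <- numeric(length(batch_ids))
      for (bi in seq_along(batch_ids)) {
        ids <- batch_ids[[bi]]
        pb <- pad_batch(seqs_t[ids])
        res <- lstm_loss_grads(
          par, pb$A, pb$lens, Yall[, ids, drop = FALSE],
          masking = config$masking,
          wts = wts_by_class[as.integer(labels[ids])]
        )
        grads <- clip_global_norm(res$grads, config$clip_norm)
        upd <- adam_step(par, grads, state, lr)
        par <- upd$par
        state <- upd$state
        losses[bi] <- res$loss
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses), lr = lr)
    }
    par
  })

  structure(
    list(
      params = fit,
      config = config,
      channels = channel_names,
      levels = gait_labels(),
      standardize = std,
      log = dplyr::bind_rows(log_rows)
    ),
    class = "gait_lstm"
  )
}

#' Predict gait class for envelope sequences
#'
#' Inference is per sequence and unpadded: each sequence is run through the
#' LSTM at its own length, so predictions never depend on batch grouping.
#' Ties in the softmax break toward the first label in the fixed ordering
#' (young before elderly).
#'
#' @param object A `gait_lstm` from [train_lstm()].
#' @param new_data A data frame with list-column `sequence`, a list of
#'   frames x channels matrices, or a single matrix.
#' @param type `"label"` (default) adds class probabilities alongside the
#'   predicted label; `"prob"` returns probabilities only.
#' @param ... Unused.
#' @return A tibble with columns `.pred_label` (unless `type = "prob"`),
#'   `.pred_young`, `.pred_elderly`.
#' @export
predict.gait_lstm <- function(object, new_data, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  seqs <- if (is.data.frame(new_data)) {
    new_data$sequence
  } else if (is.matrix(new_data)) {
    list(new_data)
  } else {
    new_data
  }
  if (length(seqs) == 0L) {
    return(tibble::tibble(
      .pred_label = factor(character(), levels = object$levels),
      .pred_young = numeric(), .pred_elderly = numeric()
    ))
  }
  C <- ncol(object$params$W)
  probs <- vapply(seqs, function(s) {
    if (is.null(dim(s))) s <- matrix(s, ncol = 1L)
    if (nrow(s) < 1L) stop("zero-length sequence", call. = FALSE)
    if (ncol(s) != C) {
      stop(sprintf(
        "sequence has %d channel(s) but the model was trained with %d",
        ncol(s), C
      ), call. = FALSE)
    }
    if (!is.null(object$standardize)) {
      s <- sweep(sweep(s, 2L, object$standardize$mean), 2L, object$standardize$sd, `/`)
    }
    pb <- pad_batch(list(t(s)))
    res <- lstm_loss_grads(object$params, pb$A, pb$lens,
      Y = matrix(c(1, 0), 2, 1), masking = TRUE, wts = 1,
      want_grads = FALSE
    )
    res$probs[, 1]
  }, numeric(2))
  if (type == "prob") {
    return(tibble::tibble(
      .pred_young = unname(probs[1, ]),
      .pred_elderly = unname(probs[2, ])
    ))
  }
  idx <- apply(probs, 2L, which.max)
  tibble::tibble(
    .pred_label = factor(object$levels[idx], levels = object$levels),
    .pred_young = unname(probs[1, ]),
    .pred_elderly = unname(probs[2, ])
  )
}

#' @export
print.gait_lstm <- function(x, ...) {
  cat(sprintf(
    "<gait_lstm> %d channel(s) [%s], %d hidden cells, %d epochs; final loss %.4f\n",
    length(x$channels), paste(x$channels, collapse = ","),
    x$config$hidden_units, nrow(x$log), x$log$loss[nrow(x$log)]
  ))
  invisible(x)
}

#' @describeIn train_lstm Per-epoch training log (`epoch`, `loss`, `lr`).
#' @param x A `gait_lstm`.
#' @param ... Unused.
#' @method tidy gait_lstm
#' @export
tidy.gait_lstm <- function(x, ...) x$log

#' @describeIn train_lstm One-row model summary.
#' @method glance gait_lstm
#' @export
glance.gait_lstm <- function(x, ...) {
  tibble::tibble(
    hidden_units = x$config$hidden_units,
    channels = length(x$channels),
    epochs = nrow(x$log),
    final_loss = x$log$loss[nrow(x$log)],
    final_lr = x$log$lr[nrow(x$log)]
  )
}
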