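#' Power-weighted mean velocity of each spectrogram frame
#'
#' The mean envelope: per frame the first moment of the power spectrum over
#' the full velocity axis (negative velocities included),
#' \eqn{v_m(t) = \sum_v v\,P(t,v) / \sum_v P(t,v)}. It tracks the torso, the
#' dominant scatterer. Frames with zero total power are flagged undefined
#' (`NA`).
#'
#' @param spec A `gait_spectrogram`.
#' @return Numeric vector of per-frame velocities (m/s), `NA` where undefined.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' sp <- compute_spectrogram(synthesize_baseband(simulate_walker(p, 3)))
#' mean(mean_envelope(sp)) # ~ torso speed
#' @export
mean_envelope <- function(spec) {
  stopifnot(inherits(spec, "gait_spectrogram"))
  tot <- rowSums(spec$power)
  if (all(tot == 0)) stop("all-zero spectrogram: mean envelope undefined", call. = FALSE)
  vm <- as.vector(spec$power %*% spec$velocities) / tot
  vm[tot == 0] <- NA_real_
  vm
}

#' Significant spectral peaks of one spectrogram frame
#'
#' A significant peak is a local maximum of the per-bin amplitude — a bin
#' strictly greater than both neighbours; for plateaus, the leftmost bin of a
#' maximal run that exceeds both run-neighbours counts once; array endpoints
#' are ineligible — whose amplitude strictly exceeds `rho` times the frame's
#' maximum amplitude. The relative threshold is applied to amplitude
#' \eqn{|S_R|}, not power.
#'
#' @param frame_amplitudes Non-negative per-bin amplitudes of one frame.
#' @param velocities Velocity grid (m/s), same length.
#' @param rho Relative amplitude threshold in (0, 1); default 0.2.
#' @return A tibble with columns `velocity` and `amplitude`, in ascending
#'   velocity order (zero rows if the frame is all zeros or no local maximum
#'   clears the threshold).
#' @examples
#' significant_peaks(c(0.1, 1, 0.2, 0.3, 0.1), -2:2, rho = 0.2)
#' @export
significant_peaks <- function(frame_amplitudes, velocities, rho = 0.2) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1) {
    stop("`rho` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(frame_amplitudes < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (length(frame_amplitudes) != length(velocities)) {
    stop("`frame_amplitudes` and `velocities` must have equal length", call. = FALSE)
  }
  idx <- local_maxima(frame_amplitudes)
  amax <- max(frame_amplitudes)
  idx <- idx[frame_amplitudes[idx] > rho * amax]
  tibble::tibble(
    velocity = velocities[idx],
    amplitude = frame_amplitudes[idx]
  )
}

# Indices of local maxima under the plateau rule: the leftmost bin of each
# maximal run of equal values that strictly exceeds both run-neighbours.
# Runs touching either array endpoint are ineligible.
local_maxima <- function(a) {
  n <- length(a)
  if (n < 3L || all(a == 0)) {
    return(integer(0))
  }
  runs <- rle(a)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  if (k < 3L) {
    return(integer(0))
  }
  mid <- 2:(k - 1L)
  is_peak <- runs$values[mid] > runs$values[mid - 1L] &
    runs$values[mid] > runs$values[mid + 1L]
  starts[mid][is_peak]
}

#' Extract the three velocity envelopes of a gait spectrogram
#'
#' Per frame: the upper envelope \eqn{v_u} is the largest significant-peak
#' velocity (tracks the swinging leg), the lower envelope \eqn{v_l} the
#' smallest (tracks the planted, stance-phase leg), and \eqn{v_m} is the
#' power-weighted mean velocity (tracks the torso). Frames with no
#' significant peak carry the previous frame's \eqn{v_u}/\eqn{v_l} forward;
#' if the very first frame has none, extraction fails.
#'
#' @param spec A `gait_spectrogram`.
#' @param rho Relative amplitude threshold in (0, 1); default 0.2.
#' @return An object of class `envelope_set`: `frame_times`, `v_u`, `v_m`,
#'   `v_l` (equal-length numeric series), `rho`, `n_carried` (count of
#'   carried-forward frames) and a `source` descriptor.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' sp <- compute_spectrogram(synthesize_baseband(simulate_walker(p, 3)))
#' env <- extract_envelopes(sp)
#' max(env$v_u) # ~ swing peak velocity
#' @export
extract_envelopes <- function(spec, rho = 0.2) {
  stopifnot(inherits(spec, "gait_spectrogram"))
  amp <- sqrt(spec$power)
  nf <- nrow(amp)
  v_u <- v_l <- numeric(nf)
  carried <- 0L
  for (j in seq_len(nf)) {
    pk <- significant_peaks(amp[j, ], spec$velocities, rho)
    if (nrow(pk) == 0L) {
      if (j == 1L) {
        stop("first frame has no significant peaks; cannot extract envelopes", call. = FALSE)
      }
      v_u[j] <- v_u[j - 1L]
      v_l[j] <- v_l[j - 1L]
      carried <- carried + 1L
    } else {
      v_u[j] <- max(pk$velocity)
      v_l[j] <- min(pk$velocity)
    }
  }
  if (carried > 0L) {
    message(sprintf("extract_envelopes: carried forward %d frame(s) with no significant peaks", carried))
  }
  structure(
    list(
      frame_times = spec$frame_times,
      v_u = v_u,
      v_m = mean_envelope(spec),
      v_l = v_l,
      rho = rho,
      n_carried = carried,
      source = sprintf("spectrogram[window=%d,hop=%d,fs=%g]", spec$window_len, spec$hop, spec$fs)
    ),
    class = "envelope_set"
  )
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf(
    "<envelope_set> %d frames, rho = %g; v_u in [%.2f, %.2f], v_m in [%.2f, %.2f], v_l in [%.2f, %.2f] m/s\n",
    length(x$frame_times), x$rho,
    min(x$v_u), max(x$v_u),
    min(x$v_m, na.rm = TRUE), max(x$v_m, na.rm = TRUE),
    min(x$v_l), max(x$v_l)
  ))
  invisible(x)
}

#' Channel sets for the classifier input conditions
#'
#' Seven fixed combinations of the three envelope series are studied as
#' classifier inputs:
#' 1 `v_u`; 2 `v_m`; 3 `v_l`; 4 `v_u, v_m`; 5 `v_u, v_l`; 6 `v_m, v_l`;
#' 7 `v_u, v_m, v_l`. Channel order is fixed as listed.
#'
#' @param condition Integer in 1..7.
#' @return Character vector of channel names.
#' @export
condition_channels <- function(condition) {
  if (length(condition) != 1L || is.na(suppressWarnings(as.integer(condition))) ||
    as.integer(condition) != condition || !(condition %in% 1:7)) {
    stop("`condition` must be an integer between 1 and 7", call. = FALSE)
  }
  switch(as.integer(condition),
    "v_u",
    "v_m",
    "v_l",
    c("v_u", "v_m"),
    c("v_u", "v_l"),
    c("v_m", "v_l"),
    c("v_u", "v_m", "v_l")
  )
}

#' Assemble the classifier input sequence for a condition
#'
#' @param env An `envelope_set`.
#' @param condition Integer in 1..7; see [condition_channels()].
#' @return A frames x channels numeric matrix with the selected envelope
#'   series as named columns, in the fixed condition order.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' sp <- compute_spectrogram(synthesize_baseband(simulate_walker(p, 3)))
#' dim(build_condition_input(extract_envelopes(sp), condition = 7))
#' @export
build_condition_input <- function(env, condition) {
  stopifnot(inherits(env, "envelope_set"))
  ch <- condition_channels(condition)
  m <- vapply(ch, function(nm) env[[nm]], numeric(length(env$frame_times)))
  matrix(m, ncol = length(ch), dimnames = list(NULL, ch))
}

#' Read / write an envelope set as columnar text
#'
#' CSV with columns `frame_time,v_u,v_m,v_l` preceded by comment header lines
#' `# rho=` and `# source=`. This is the interchange format between the
#' envelope-extraction and classification stages.
#'
#' @param env An `envelope_set`.
#' @param path File path.
#' @return `write_envelopes()` returns `path` invisibly; `read_envelopes()`
#'   returns an `envelope_set`.
#' @export
write_envelopes <- function(env, path) {
  stopifnot(inherits(env, "envelope_set"))
  writeLines(c(sprintf("# rho=%.10g", env$rho), sprintf("# source=%s", env$source)), path)
  readr::write_csv(tidy(env), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_envelopes
#' @export
read_envelopes <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  get_field <- function(key) {
    line <- grep(sprintf("^# %s=", key), header, value = TRUE)
    if (length(line) == 0L) NA_character_ else sub(sprintf("^# %s=", key), "", line[1])
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  structure(
    list(
      frame_times = df$frame_time,
      v_u = df$v_u, v_m = df$v_m, v_l = df$v_l,
      rho = as.numeric(get_field("rho")),
      n_carried = NA_integer_,
      source = get_field("source") %||% "unknown"
    ),
    class = "envelope_set"
  )
}

#' @describeIn extract_envelopes Tabular view with columns `frame_time`,
#'   `v_u`, `v_m`, `v_l`.
#' @param x An `envelope_set`.
#' @param ... Unused.
#' @method tidy envelope_set
#' @export
tidy.envelope_set <- function(x, ...) {
  tibble::tibble(
    frame_time = x$frame_times,
    v_u = x$v_u, v_m = x$v_m, v_l = x$v_l
  )
}

#' @describeIn extract_envelopes Plot the three envelope series against time.
#' @param object An `envelope_set`.
#' @method autoplot envelope_set
#' @export
autoplot.envelope_set <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), -"frame_time",
    names_to = "envelope", values_to = "velocity"
  )
  df$envelope <- factor(df$envelope, levels = c("v_u", "v_m", "v_l"))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame_time, .data$velocity, colour = .data$envelope)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "radial velocity (m/s)", colour = NULL) +
    ggplot2::theme_minimal()
}
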