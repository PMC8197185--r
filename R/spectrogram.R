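#' Time-velocity spectrogram of a baseband radar signal
#'
#' Short-time Fourier transform with a symmetric Hamming window
#' (\eqn{0.54 - 0.46\cos(2\pi n/(L-1))}, default length 128 samples) and an
#' unnormalized forward DFT. Frequency bins are rotated so that zero Doppler
#' is central and relabelled as radial velocity through
#' \eqn{v = f_d \lambda / 2}; motion toward the radar maps to positive
#' velocity. Frames are center-aligned and frames that would need samples
#' outside the signal are dropped, so all frame times are interior.
#'
#' @param signal A [baseband_signal()] (length at least `window_len`).
#' @param window_len Window length in samples (default 128).
#' @param hop Hop between consecutive frames in samples (default 8; at 600 Hz
#'   this gives 75 frames/s, so a two-cycle gait interval of about 2 s spans
#'   roughly 150 frames).
#' @param config A [radar_config()] used for the velocity axis.
#'
#' @return An object of class `gait_spectrogram`: `frame_times` (s, window
#'   centers), `velocities` (m/s, increasing, zero-centered, spanning
#'   \eqn{(-f_s/2, f_s/2]} in Doppler), `power` (frames x bins matrix of
#'   \eqn{|S_R|^2}), plus `window_len`, `hop`, `fs` and `config`.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' sig <- synthesize_baseband(simulate_walker(p, n_cycles = 3))
#' sp <- compute_spectrogram(sig)
#' dim(sp$power)
#' @export
compute_spectrogram <- function(signal, window_len = 128, hop = 8,
                                config = radar_config()) {
  stopifnot(inherits(signal, "baseband_signal"), inherits(config, "radar_config"))
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (hop < 1L) stop("`hop` must be at least 1 sample", call. = FALSE)
  if (signal$n < window_len) {
    stop(sprintf(
      "signal has %d samples but the window needs at least %d",
      signal$n, window_len
    ), call. = FALSE)
  }
  w <- hamming_window(window_len)
  starts <- seq.int(1L, signal$n - window_len + 1L, by = hop)
  nf <- length(starts)

  # frequency of DFT bin k (0-based): k*fs/L for k <= L/2, else (k-L)*fs/L
  k <- 0:(window_len - 1L)
  freqs <- ifelse(k > window_len / 2, k - window_len, k) * signal$fs / window_len
  ord <- order(freqs)

  power <- matrix(0, nrow = nf, ncol = window_len)
  for (j in seq_len(nf)) {
    seg <- signal$samples[starts[j]:(starts[j] + window_len - 1L)]
    spec <- stats::fft(w * seg)
    power[j, ] <- (Mod(spec)^2)[ord]
  }

  structure(
    list(
      frame_times = (starts - 1 + (window_len - 1) / 2) / signal$fs,
      velocities = doppler_velocity(freqs[ord], config),
      power = power,
      window_len = window_len,
      hop = hop,
      fs = signal$fs,
      config = config
    ),
    class = "gait_spectrogram"
  )
}

hamming_window <- function(L) {
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Radial-velocity bin spacing of a spectrogram
#'
#' @param spec A `gait_spectrogram`.
#' @return Bin width in m/s, \eqn{(f_s / L)\,\lambda/2}.
#' @export
velocity_resolution <- function(spec) {
  stopifnot(inherits(spec, "gait_spectrogram"))
  (spec$fs / spec$window_len) * spec$config$wavelength / 2
}

#' @export
print.gait_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<gait_spectrogram> %d frames x %d velocity bins, hop %d, window %d, dv = %.4f m/s\n",
    nrow(x$power), ncol(x$power), x$hop, x$window_len, velocity_resolution(x)
  ))
  invisible(x)
}

#' Estimate the gait-cycle period from a spectrogram
#'
#' The per-frame velocity profile of a walker repeats every step. The
#' estimator demeans each velocity bin's time series, computes the lagged
#' correlation of the resulting profile matrix with itself, and takes the
#' first significant local maximum as the step period; the gait cycle is two
#' steps. (The per-frame total power itself is nearly constant — each
#' scatterer contributes its full reflected power to every frame regardless
#' of spectral smear — so periodicity must be read from the profile shape,
#' not the total.)
#'
#' @param spec A `gait_spectrogram`.
#' @param min_period,max_period Admissible step-period range in seconds.
#' @param min_corr Minimum normalized correlation for a lag peak to count as
#'   significant.
#' @return List with `cycle` (s), `step` (s) and `corr` (peak correlation).
#' @export
estimate_gait_cycle <- function(spec, min_period = 0.25, max_period = 1.5,
                                min_corr = 0.2) {
  stopifnot(inherits(spec, "gait_spectrogram"))
  X <- scale(spec$power, center = TRUE, scale = FALSE)
  nf <- nrow(X)
  a0 <- sum(X^2)
  if (a0 <= 0 || a0 < 1e-12 * sum(spec$power^2)) {
    stop("no significant periodicity found (time-constant spectrogram); select the analysis interval manually",
      call. = FALSE
    )
  }
  dt <- spec$hop / spec$fs
  lag_max <- min(nf - 2L, ceiling(max_period / dt))
  r <- vapply(seq_len(lag_max), function(lag) {
    sum(X[1:(nf - lag), ] * X[(1 + lag):nf, ]) / a0
  }, numeric(1))

  lo <- max(2L, floor(min_period / dt))
  peak_lag <- NA_integer_
  for (lag in lo:(lag_max - 1L)) {
    if (r[lag] > r[lag - 1L] && r[lag] >= r[lag + 1L] && r[lag] > min_corr) {
      peak_lag <- lag
      break
    }
  }
  if (is.na(peak_lag)) {
    stop("no significant periodicity found; select the analysis interval manually",
      call. = FALSE
    )
  }
  step <- peak_lag * dt
  list(cycle = 2 * step, step = step, corr = r[peak_lag])
}

#' Crop a spectrogram to a steady-state analysis interval
#'
#' Estimates the gait-cycle period with [estimate_gait_cycle()] and keeps
#' `n_cycles` consecutive periods centered in the recording.
#'
#' @param spec A `gait_spectrogram`.
#' @param n_cycles Number of gait cycles to keep (default 2).
#' @param ... Passed to [estimate_gait_cycle()].
#' @return The cropped `gait_spectrogram`, with the period estimate attached
#'   as field `cycle_estimate`.
#' @export
select_analysis_interval <- function(spec, n_cycles = 2, ...) {
  stopifnot(inherits(spec, "gait_spectrogram"))
  est <- estimate_gait_cycle(spec, ...)
  span <- n_cycles * est$cycle
  t_mid <- (min(spec$frame_times) + max(spec$frame_times)) / 2
  keep <- spec$frame_times >= t_mid - span / 2 & spec$frame_times < t_mid + span / 2
  if (sum(keep) < 2L) {
    stop(sprintf(
      "recording too short for %d cycles of %.2f s; select the analysis interval manually",
      n_cycles, est$cycle
    ), call. = FALSE)
  }
  out <- spec
  out$frame_times <- spec$frame_times[keep]
  out$power <- spec$power[keep, , drop = FALSE]
  out$cycle_estimate <- est
  out
}

#' @describeIn compute_spectrogram Long tabular view with columns
#'   `frame_time`, `velocity`, `power`.
#' @param x A `gait_spectrogram`.
#' @param ... Unused.
#' @method tidy gait_spectrogram
#' @export
tidy.gait_spectrogram <- function(x, ...) {
  tibble::tibble(
    frame_time = rep(x$frame_times, times = ncol(x$power)),
    velocity = rep(x$velocities, each = nrow(x$power)),
    power = as.vector(x$power)
  )
}

#' @describeIn compute_spectrogram Plot the spectrogram as a time-velocity
#'   power map on a dB scale.
#' @param object A `gait_spectrogram`.
#' @method autoplot gait_spectrogram
#' @export
autoplot.gait_spectrogram <- function(object, ...) {
  df <- tidy(object)
  floor_db <- max(df$power) * 1e-6
  df$power_db <- 10 * log10(pmax(df$power, floor_db))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame_time, .data$velocity, fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "time (s)", y = "radial velocity (m/s)") +
    ggplot2::theme_minimal()
}
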