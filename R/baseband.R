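#' Synthesize the demodulated complex baseband radar echo
#'
#' Sums the echoes of all scatterers in a trajectory set,
#' \deqn{s_R(t) = \sum_i \eta_i A \exp\{j \phi_i(t)\}, \qquad
#'       \phi_i(t) = -\frac{4\pi R_i(t)}{\lambda},}
#' the time-varying-range generalization of the constant-velocity point
#' scatterer phase (for \eqn{R_i(t) = R_i - v_{di} t} it reduces to the
#' familiar \eqn{-2\pi(2R_i/\lambda - 2 v_{di} t/\lambda)}). Range attenuation
#' is deliberately omitted: the \eqn{\eta_i} are fixed amplitude ratios.
#' Optionally adds circular complex white Gaussian noise.
#'
#' @param traj A `scatterer_trajectories` object sampled at `config$fs`.
#' @param config A [radar_config()].
#' @param noise_sd Standard deviation of the additive noise per real/imaginary
#'   component (amplitude units of \eqn{A}); 0 for a noise-free echo.
#' @param rng_seed Integer seed for the noise draw (ignored when
#'   `noise_sd = 0`).
#'
#' @return An object of class `baseband_signal`: complex `samples`, `fs`,
#'   `n`, and a `provenance` string.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' traj <- simulate_walker(p, n_cycles = 3)
#' sig <- synthesize_baseband(traj, noise_sd = 0.05, rng_seed = 2)
#' sig$n
#' @export
synthesize_baseband <- function(traj, config = radar_config(), noise_sd = 0,
                                rng_seed = NULL) {
  stopifnot(inherits(traj, "scatterer_trajectories"), inherits(config, "radar_config"))
  if (!isTRUE(all.equal(traj$fs, config$fs))) {
    stop(sprintf(
      "trajectory sampling rate (%g Hz) does not match radar config fs (%g Hz)",
      traj$fs, config$fs
    ), call. = FALSE)
  }
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (any(traj$ranges <= 0)) stop("all ranges must be positive", call. = FALSE)

  fd_max <- max(abs(doppler_frequency(traj$radial_velocities, config)))
  if (fd_max > config$fs / 2) {
    warning(sprintf(
      "max Doppler frequency %.1f Hz exceeds fs/2 = %.1f Hz; the synthesized signal aliases",
      fd_max, config$fs / 2
    ), call. = FALSE)
  }

  phases <- -4 * pi * traj$ranges / config$wavelength
  eta <- traj$reflectivities
  samples <- as.complex(exp(1i * phases) %*% (eta * config$amplitude))
  samples <- samples * exp(1i * config$phi0)

  if (noise_sd > 0) {
    n <- length(samples)
    noise <- with_seed(
      rng_seed %||% 0L,
      complex(
        real = stats::rnorm(n, sd = noise_sd),
        imaginary = stats::rnorm(n, sd = noise_sd)
      )
    )
    samples <- samples + noise
  }

  baseband_signal(
    samples = samples, fs = config$fs,
    provenance = sprintf(
      "simulated:%s;noise_sd=%g;seed=%s",
      traj$true_params$label, noise_sd,
      if (is.null(rng_seed)) "NA" else as.character(rng_seed)
    )
  )
}

#' Construct a baseband signal object
#'
#' @param samples Complex vector of demodulated I/Q samples.
#' @param fs Sampling frequency in Hz.
#' @param provenance Free-text origin tag (trajectory/seed reference, or
#'   `"measured"` for real recordings).
#' @return An object of class `baseband_signal`.
#' @export
baseband_signal <- function(samples, fs, provenance = "measured") {
  if (!is.complex(samples)) samples <- as.complex(samples)
  assert_scalar_number(fs, "fs", positive = TRUE)
  structure(
    list(samples = samples, fs = fs, n = length(samples), provenance = provenance),
    class = "baseband_signal"
  )
}

#' @export
print.baseband_signal <- function(x, ...) {
  cat(sprintf(
    "<baseband_signal> %d complex samples at %g Hz (%.2f s), provenance: %s\n",
    x$n, x$fs, x$n / x$fs, x$provenance
  ))
  invisible(x)
}

#' Read / write a baseband signal as columnar text
#'
#' The interchange format is a CSV with columns `t,I,Q` preceded by comment
#' header lines `# fs=<Hz>` and `# provenance=<text>`.
#'
#' @param signal A `baseband_signal`.
#' @param path File path.
#' @return `write_baseband()` returns `path` invisibly; `read_baseband()`
#'   returns a `baseband_signal`.
#' @export
write_baseband <- function(signal, path) {
  stopifnot(inherits(signal, "baseband_signal"))
  header <- c(
    sprintf("# fs=%.10g", signal$fs),
    sprintf("# provenance=%s", signal$provenance)
  )
  writeLines(header, path)
  df <- tibble::tibble(
    t = (seq_len(signal$n) - 1L) / signal$fs,
    I = Re(signal$samples),
    Q = Im(signal$samples)
  )
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_baseband
#' @export
read_baseband <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  get_field <- function(key) {
    line <- grep(sprintf("^# %s=", key), header, value = TRUE)
    if (length(line) == 0L) {
      return(NA_character_)
    }
    sub(sprintf("^# %s=", key), "", line[1])
  }
  fs <- as.numeric(get_field("fs"))
  if (!is.finite(fs)) stop("baseband file header is missing `# fs=`", call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  baseband_signal(
    samples = complex(real = df$I, imaginary = df$Q),
    fs = fs,
    provenance = get_field("provenance") %||% "unknown"
  )
}
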