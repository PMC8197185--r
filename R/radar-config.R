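#' Radar configuration
#'
#' Parameters of the continuous-wave micro-Doppler radar: carrier frequency,
#' baseband sampling rate, transmit amplitude and initial phase. The carrier
#' wavelength is derived as \eqn{\lambda = c / f_0} with
#' \eqn{c = 299792458} m/s.
#'
#' @param f0 Carrier frequency in Hz. Default 24 GHz, a common band for
#'   short-range CW Doppler sensors.
#' @param fs Baseband sampling frequency in Hz. Default 600 Hz, which bounds
#'   the unambiguous (Nyquist) radial velocity at
#'   \eqn{(f_s/2)\,\lambda/2 \approx 1.87} m/s for a 24 GHz carrier.
#' @param amplitude Unitless transmit amplitude \eqn{A}. Default 1.
#' @param phi0 Initial carrier phase in radians. Default 0.
#'
#' @return An object of class `radar_config`: a list with fields `f0`, `fs`,
#'   `amplitude`, `phi0` and the derived `wavelength` (m).
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength        # c / 24e9, about 12.5 mm
#' nyquist_velocity(cfg) # about 1.87 m/s
#' @export
radar_config <- function(f0 = 24e9, fs = 600, amplitude = 1, phi0 = 0) {
  assert_scalar_number(f0, "f0", positive = TRUE)
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(amplitude, "amplitude")
  assert_scalar_number(phi0, "phi0")
  structure(
    list(
      f0 = f0,
      fs = fs,
      amplitude = amplitude,
      phi0 = phi0,
      wavelength = speed_of_light() / f0
    ),
    class = "radar_config"
  )
}

speed_of_light <- function() 299792458

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> f0 = %.4g Hz, fs = %g Hz, lambda = %.6g m, v_nyq = %.4f m/s\n",
    x$f0, x$fs, x$wavelength, nyquist_velocity(x)
  ))
  invisible(x)
}

#' Doppler frequency of a radial velocity
#'
#' Converts a radial velocity into the Doppler shift of a monostatic CW radar,
#' \eqn{f_d = 2 v / \lambda}. Motion toward the radar (positive `v`) gives a
#' positive Doppler shift.
#'
#' @param v Radial velocity in m/s (vectorised).
#' @param config A [radar_config()].
#' @return Doppler frequency in Hz, same length as `v`.
#' @examples
#' doppler_frequency(1, radar_config())   # about 160.11 Hz at 24 GHz
#' @export
doppler_frequency <- function(v, config = radar_config()) {
  stopifnot(inherits(config, "radar_config"))
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop("`v` must be finite numeric", call. = FALSE)
  }
  2 * v / config$wavelength
}

#' Velocity corresponding to a Doppler frequency
#'
#' Inverse of [doppler_frequency()]: \eqn{v = f_d \lambda / 2}.
#'
#' @param fd Doppler frequency in Hz (vectorised).
#' @inheritParams doppler_frequency
#' @return Radial velocity in m/s.
#' @export
doppler_velocity <- function(fd, config = radar_config()) {
  stopifnot(inherits(config, "radar_config"))
  fd * config$wavelength / 2
}

#' Largest unambiguous radial velocity
#'
#' The Nyquist velocity \eqn{v_{max} = (f_s/2)\,\lambda/2} set by the baseband
#' sampling rate; radial velocities at or beyond it alias in the spectrogram.
#'
#' @inheritParams doppler_frequency
#' @return Velocity in m/s.
#' @export
nyquist_velocity <- function(config = radar_config()) {
  stopifnot(inherits(config, "radar_config"))
  (config$fs / 2) * config$wavelength / 2
}
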