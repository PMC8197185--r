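#' Simulate multi-scatterer kinematics of a walking human
#'
#' Generates radial range and velocity tracks for a five-scatterer walker
#' (torso, two feet, two tibiae) approaching the radar. The torso moves at
#' the realized walking speed with a triangular within-cycle speed
#' oscillation (two oscillations per gait cycle, one per step), phase-locked
#' to the footfalls. Each foot cycles through stance (radial velocity within
#' the stance residual of a slow forward creep), a cosine-ramped swing-
#' velocity plateau peaking at the realized swing-peak velocity, and a
#' terminal-swing hover before heel strike. The left and right feet are
#' offset by exactly half a gait cycle, so at every instant one foot echoes
#' near zero velocity — the planted-leg return that anchors the lower
#' envelope of a measured gait spectrogram. Each tibia moves as the kinematic
#' midpoint of the torso and its foot, giving the intermediate micro-Doppler
#' amplitude of a shank.
#'
#' The waveform shapes are chosen for their spectral behaviour as much as
#' their kinematics: the triangle oscillation keeps the torso ridge smeared
#' over several Doppler bins in every analysis window, and the foot dwells
#' are near-tones, so the weak foot echoes stay detectable against the
#' dominant torso under a relative amplitude threshold (see the package
#' vignette for the full design rationale).
#'
#' Ranges are obtained by trapezoidal integration of the (negative) radial
#' velocities, so velocity is the negative time-derivative of range by
#' construction. Limb displacement is deliberately not constrained to match
#' the torso displacement per cycle: a displacement-consistent foot at
#' walking speed would need swing peaks of 3 m/s and more, beyond the
#' unambiguous velocity of a 600 Hz / 24 GHz radar.
#'
#' As a degenerate special case, `swing_peak_velocity = 0` denotes a rigid
#' (non-articulated) scatterer cluster: all five scatterers then ride the
#' torso track. This is the natural zero-articulation limit used for
#' validation.
#'
#' @param params A `gait_class_params` realization from
#'   [sample_class_params()] (or built manually).
#' @param n_cycles Number of gait cycles to generate (at least 2).
#' @param config A [radar_config()]; supplies the sampling rate and the
#'   Nyquist velocity guard.
#' @param start_range Initial torso range in m; must keep all ranges positive
#'   over the walk.
#' @param rng_seed Optional integer seed controlling the random initial gait
#'   phase; `NULL` starts at phase zero.
#' @param tibia_torso_mix Weight of the torso track in each tibia's velocity
#'   (the remainder follows the foot); 0.5 is the shank midpoint.
#'
#' @return An object of class `scatterer_trajectories`: fields `times` (s),
#'   `ranges` and `radial_velocities` (matrices, samples x 5 scatterers),
#'   `reflectivities`, `roles`, `fs`, and `true_params`.
#' @examples
#' p <- sample_class_params("young", rng_seed = 1)
#' traj <- simulate_walker(p, n_cycles = 4)
#' max(traj$radial_velocities[, "right_foot"]) # ~ p$swing_peak_velocity
#' @export
simulate_walker <- function(params, n_cycles = 5, config = radar_config(),
                            start_range = 9, rng_seed = NULL,
                            tibia_torso_mix = 0.5) {
  stopifnot(inherits(params, "gait_class_params"), inherits(config, "radar_config"))
  if (n_cycles < 2) stop("`n_cycles` must be at least 2", call. = FALSE)
  fs <- config$fs
  Tc <- params$cycle_duration
  n <- as.integer(round(n_cycles * Tc * fs)) + 1L
  times <- (seq_len(n) - 1L) / fs

  v_nyq <- nyquist_velocity(config)
  v_peak_reachable <- max(
    params$torso_speed + params$torso_fluct_amp,
    params$swing_peak_velocity,
    (params$torso_speed + params$torso_fluct_amp + params$swing_peak_velocity) / 2
  )
  if (v_peak_reachable >= v_nyq) {
    stop(sprintf(
      "parameters imply radial velocity %.3f m/s >= Nyquist velocity %.3f m/s; refusing to generate aliased ground truth",
      v_peak_reachable, v_nyq
    ), call. = FALSE)
  }

  phase0 <- if (is.null(rng_seed)) 0 else with_seed(rng_seed, stats::runif(1L))

  # The oscillation is phase-locked to the gait so its velocity extrema fall
  # midway through each foot's slow (stance + hover) period, not at the
  # instants where the slow-foot role hands over between feet: the extremum
  # frames concentrate the torso's spectral ridge (a fold caustic of the
  # velocity turnaround), and only a foot in full dwell can match it.
  v_torso <- params$torso_speed +
    params$torso_fluct_amp *
      torso_oscillation(4 * pi * (times / Tc + phase0 - params$stance_duty + 0.02))

  rigid <- params$swing_peak_velocity == 0
  if (rigid) {
    v_rfoot <- v_lfoot <- v_torso
  } else {
    v_rfoot <- foot_velocity((times / Tc + phase0) %% 1, params)
    v_lfoot <- foot_velocity((times / Tc + phase0 + 0.5) %% 1, params)
  }
  a <- tibia_torso_mix
  v_rtib <- a * v_torso + (1 - a) * v_rfoot
  v_ltib <- a * v_torso + (1 - a) * v_lfoot

  vel <- cbind(
    torso = v_torso,
    left_foot = v_lfoot, right_foot = v_rfoot,
    left_tibia = v_ltib, right_tibia = v_rtib
  )

  # R_i(t) = R_i(0) - integral of v_i (approach => decreasing range)
  disp <- apply(vel, 2L, cumtrapz_dt, dt = 1 / fs)
  r0 <- c(
    torso = start_range,
    left_foot = start_range + 0.3, right_foot = start_range - 0.1,
    left_tibia = start_range + 0.25, right_tibia = start_range - 0.05
  )
  ranges <- sweep(-disp, 2L, r0[colnames(vel)], `+`)
  if (any(ranges <= 0)) {
    stop("`start_range` too small: range reaches zero during the walk", call. = FALSE)
  }

  eta <- params$limb_reflectivities
  structure(
    list(
      times = times,
      ranges = ranges,
      radial_velocities = vel,
      reflectivities = c(
        torso = unname(eta["torso"]),
        left_foot = unname(eta["foot"]), right_foot = unname(eta["foot"]),
        left_tibia = unname(eta["tibia"]), right_tibia = unname(eta["tibia"])
      ),
      roles = colnames(vel),
      fs = fs,
      true_params = params
    ),
    class = "scatterer_trajectories"
  )
}

# Within-cycle torso speed oscillation: a unit-amplitude triangle wave, two
# oscillations per gait cycle. Its slew rate is constant, so the torso's
# spectral ridge is uniformly smeared over several Doppler bins in every
# analysis window; a sinusoid would collapse to a near-single-bin tone twice
# per step, and those frames would raise the relative peak threshold above
# the much weaker foot echoes.
torso_oscillation <- function(x) {
  (2 / pi) * asin(sin(x))
}

# Radial velocity of a foot over one normalized gait cycle u in [0, 1).
# Two regimes:
#   swing pulse [d, d + 0.5): cosine-ramped plateau at the swing peak
#     velocity — the sustained return of a swinging foot at the high-velocity
#     edge of a gait spectrogram;
#   slow span [d + 0.5, 1) (terminal-swing hover) flowing into [0, d)
#     (stance): the return drifts linearly from ~0.01 m/s up to the stance
#     residual velocity, emulating the heel-to-toe roll of the echo centroid
#     across a planted foot. The drift rate (residual / half cycle, about
#     0.2 m/s^2) is slow enough that the echo stays a near-tone within any
#     analysis window, so the planted foot remains detectable under the
#     relative peak threshold; the resulting lower envelope is a per-step
#     sawtooth whose height is the class's stance-phase velocity scale.
# Because the feet are half a cycle apart, the slow spans tile the cycle: at
# every instant one foot echoes near zero velocity, anchoring the lower
# envelope, and the outgoing (fast end of ramp) and incoming (slow end) feet
# sit a few Doppler bins apart at the hand-over, so their echoes never share
# a bin and cannot cancel coherently.
foot_velocity <- function(u, params, ramp = 0.05, dwell_base = 0.03,
                          swing_span = 0.5) {
  d <- params$stance_duty
  v <- numeric(length(u))
  sw <- u >= d & u < d + swing_span
  w <- (u[sw] - d) / swing_span
  shape <- rep(1, length(w))
  shape[w < ramp] <- 0.5 * (1 - cos(pi * w[w < ramp] / ramp))
  hi <- w > 1 - ramp
  shape[hi] <- 0.5 * (1 - cos(pi * (1 - w[hi]) / ramp))
  v[sw] <- params$swing_peak_velocity * shape
  # dwell progress: 0 at the start of hover, 1 at toe off. The two feet's
  # dwell spans tile the cycle exactly (swing_span = 0.5), so precisely one
  # foot is slow at any instant — overlapping dwells would double the
  # slow-leg power deficit of the mean envelope right at the hand-over
  # frames. Both profile edges sit at the same base level so hand-overs
  # look alike; the
  # small tail wiggle makes the outgoing and incoming echoes differ slightly
  # in frequency, so their relative phase rotates within a window and they
  # cannot cancel coherently. The mid-dwell tent, whose height is the
  # class's stance-phase velocity scale, is the discriminative structure of
  # the lower envelope (heel-to-toe roll of the echo centroid across the
  # planted foot).
  s <- numeric(length(u))
  hov <- u >= d + swing_span
  s[hov] <- (u[hov] - d - swing_span) / (1 - swing_span)
  st <- u < d
  s[st] <- (1 - swing_span - d + u[st]) / (1 - swing_span)
  dw <- hov | st
  sdw <- s[dw]
  tent_amp <- max(params$stance_residual_velocity - dwell_base, 0)
  bump <- ifelse(sdw >= 0.12 & sdw <= 0.88,
    0.5 * (1 - cos(2 * pi * (sdw - 0.12) / 0.76)), 0
  )
  wiggle <- ifelse(sdw > 0.88, 0.01 * sin(pi * (sdw - 0.88) / 0.12)^2, 0)
  v[dw] <- dwell_base + tent_amp * bump + wiggle
  v
}

# Cumulative trapezoidal integral on a uniform grid, starting at 0.
cumtrapz_dt <- function(v, dt) {
  n <- length(v)
  c(0, cumsum((v[-1] + v[-n]) / 2) * dt)
}

#' @export
print.scatterer_trajectories <- function(x, ...) {
  cat(sprintf(
    "<scatterer_trajectories> %d samples at %g Hz (%.2f s), 5 scatterers, class %s\n",
    length(x$times), x$fs, max(x$times), x$true_params$label
  ))
  invisible(x)
}

#' @describeIn simulate_walker Tabular view: one row per sample and scatterer
#'   with columns `time`, `role`, `range`, `radial_velocity`, `reflectivity`.
#' @param x A `scatterer_trajectories` object.
#' @param ... Unused.
#' @method tidy scatterer_trajectories
#' @export
tidy.scatterer_trajectories <- function(x, ...) {
  purrr::map_dfr(seq_along(x$roles), function(i) {
    tibble::tibble(
      time = x$times,
      role = x$roles[i],
      range = x$ranges[, i],
      radial_velocity = x$radial_velocities[, i],
      reflectivity = x$reflectivities[i]
    )
  })
}
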