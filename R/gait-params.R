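#' Class-conditional gait parameter distributions
#'
#' A `gait_class_config` describes the population distribution of gait
#' parameters for one class of walkers (young or elderly); a draw from it
#' ([sample_class_params()]) gives the realized parameters of one participant.
#' The shipped defaults encode the expected aging pattern — slower torso,
#' lower swing-velocity peaks, longer gait cycles, longer stance duty and a
#' flatter stance-phase velocity profile of the planted foot — and are
#' configuration values for the simulator, not measured effect sizes of any
#' cohort.
#'
#' All velocities are radial (line-of-sight) in m/s; durations in seconds.
#' Limb reflectivities are unitless amplitude ratios \eqn{\eta \in (0, 1]}.
#' The torso dominates (\eqn{\eta = 1}); tibiae and feet are weak enough that
#' the power-weighted mean velocity of the spectrogram tracks the torso, yet
#' strong enough that foot echoes clear the relative peak-detection threshold.
#'
#' @param label Class label, `"young"` or `"elderly"`.
#' @param torso_speed_mean,torso_speed_sd Population mean and SD of the
#'   steady walking speed (m/s).
#' @param torso_fluct_amp Amplitude of the within-cycle torso speed
#'   oscillation (m/s); the torso oscillates twice per gait cycle (once per
#'   step).
#' @param cycle_duration_mean,cycle_duration_sd Gait-cycle (stride) duration
#'   distribution (s).
#' @param swing_peak_velocity_mean,swing_peak_velocity_sd Peak radial velocity
#'   of the swinging foot (m/s). Must stay below the radar's Nyquist velocity.
#' @param stance_residual_velocity Radial-velocity scale of the planted foot
#'   during stance (m/s).
#' @param stance_duty Fraction of the gait cycle each foot spends in stance.
#' @param limb_reflectivities Named numeric vector with entries `torso`,
#'   `tibia`, `foot`, each in (0, 1].
#'
#' @return An object of class `gait_class_config`.
#' @seealso [gait_default_config()], [sample_class_params()],
#'   [simulate_walker()]
#' @export
gait_class_config <- function(label,
                              torso_speed_mean,
                              torso_speed_sd,
                              torso_fluct_amp,
                              cycle_duration_mean,
                              cycle_duration_sd,
                              swing_peak_velocity_mean,
                              swing_peak_velocity_sd,
                              stance_residual_velocity,
                              stance_duty = 0.4,
                              limb_reflectivities = c(torso = 1, tibia = 0.10, foot = 0.22)) {
  label <- check_gait_label(label)
  for (nm in c(
    "torso_speed_mean", "torso_speed_sd", "torso_fluct_amp",
    "cycle_duration_mean", "cycle_duration_sd",
    "swing_peak_velocity_mean", "swing_peak_velocity_sd",
    "stance_residual_velocity", "stance_duty"
  )) {
    assert_scalar_number(get(nm), nm)
  }
  if (torso_speed_mean <= 0 || cycle_duration_mean <= 0) {
    stop("mean speeds and durations must be strictly positive", call. = FALSE)
  }
  if (swing_peak_velocity_mean <= torso_speed_mean) {
    stop("`swing_peak_velocity_mean` must exceed `torso_speed_mean` (the swing leg overtakes the torso)",
      call. = FALSE
    )
  }
  if (stance_duty < 0.4 || stance_duty > 0.5) {
    stop("`stance_duty` must lie in [0.4, 0.5] (the swing pulse occupies the half-cycle after toe off)", call. = FALSE)
  }
  eta <- limb_reflectivities
  if (!is.numeric(eta) || !all(c("torso", "tibia", "foot") %in% names(eta)) ||
    any(eta <= 0) || any(eta > 1)) {
    stop("`limb_reflectivities` must be named (torso, tibia, foot) with values in (0, 1]",
      call. = FALSE
    )
  }
  structure(
    list(
      label = label,
      torso_speed_mean = torso_speed_mean,
      torso_speed_sd = torso_speed_sd,
      torso_fluct_amp = torso_fluct_amp,
      cycle_duration_mean = cycle_duration_mean,
      cycle_duration_sd = cycle_duration_sd,
      swing_peak_velocity_mean = swing_peak_velocity_mean,
      swing_peak_velocity_sd = swing_peak_velocity_sd,
      stance_residual_velocity = stance_residual_velocity,
      stance_duty = stance_duty,
      limb_reflectivities = eta[c("torso", "tibia", "foot")]
    ),
    class = "gait_class_config"
  )
}

gait_labels <- function() c("young", "elderly")

check_gait_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !(label %in% gait_labels())) {
    stop(
      sprintf(
        "unknown gait class label %s; admissible labels are: %s",
        deparse(substitute(label)), paste(gait_labels(), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  label
}

#' Default simulator configuration for both gait classes
#'
#' @return Named list with `young` and `elderly` [gait_class_config()] entries.
#' @examples
#' cfg <- gait_default_config()
#' cfg$elderly$torso_speed_mean  # 1.0 m/s
#' @export
gait_default_config <- function() {
  list(
    young = gait_class_config(
      label = "young",
      torso_speed_mean = 1.3, torso_speed_sd = 0.10,
      torso_fluct_amp = 0.30,
      cycle_duration_mean = 1.05, cycle_duration_sd = 0.05,
      swing_peak_velocity_mean = 1.7, swing_peak_velocity_sd = 0.10,
      stance_residual_velocity = 0.10,
      stance_duty = 0.40
    ),
    elderly = gait_class_config(
      label = "elderly",
      torso_speed_mean = 1.0, torso_speed_sd = 0.15,
      torso_fluct_amp = 0.30,
      cycle_duration_mean = 1.15, cycle_duration_sd = 0.05,
      swing_peak_velocity_mean = 1.4, swing_peak_velocity_sd = 0.10,
      stance_residual_velocity = 0.04,
      stance_duty = 0.44
    )
  )
}

#' Read / write a gait simulator configuration file
#'
#' The configuration is stored as YAML with one section per class under a
#' top-level `gait` key (`gait: young: ...`, `gait: elderly: ...`).
#'
#' @param path File path.
#' @return `read_gait_config()` returns the named list of
#'   [gait_class_config()] objects; `write_gait_config()` returns `path`
#'   invisibly.
#' @examples
#' cfg <- read_gait_config(
#'   system.file("extdata", "gait_config_default.yaml", package = "gaitdoppler")
#' )
#' cfg$young$torso_speed_mean
#' @export
read_gait_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$gait)) stop("config file has no top-level `gait` key", call. = FALSE)
  out <- lapply(names(raw$gait), function(lbl) {
    fields <- raw$gait[[lbl]]
    fields$limb_reflectivities <- unlist(fields$limb_reflectivities)
    do.call(gait_class_config, c(list(label = lbl), fields))
  })
  stats::setNames(out, names(raw$gait))
}

#' @param config Named list of [gait_class_config()] objects (one per class).
#' @rdname read_gait_config
#' @export
write_gait_config <- function(config, path) {
  body <- lapply(config, function(cc) {
    x <- unclass(cc)
    x$label <- NULL
    x$limb_reflectivities <- as.list(x$limb_reflectivities)
    x
  })
  yaml::write_yaml(list(gait = body), path)
  invisible(path)
}

#' Draw per-participant gait parameters for a class
#'
#' Samples one participant's realized gait parameters from the configured
#' class distribution. Speeds and durations are drawn from truncated normal
#' distributions, symmetric about the mean where a cap binds (so configured
#' means are preserved) and capped so no achievable radial velocity can
#' alias; the swing-peak draw is floored at the realized torso band so the
#' swing leg always overtakes the torso, which keeps the upper-envelope
#' geometry well defined and skews swing peaks slightly upward for the
#' fastest walkers.
#'
#' @param label `"young"` or `"elderly"`.
#' @param rng_seed Integer seed; identical seeds give identical draws.
#' @param config Named list of class configurations, as from
#'   [gait_default_config()] or [read_gait_config()].
#' @param v_max Velocity cap (m/s); draws are kept strictly below it. Defaults
#'   to 98% of the Nyquist velocity of the default radar so that generated
#'   kinematics can never alias.
#'
#' @return A `gait_class_params` object: realized scalars `torso_speed`,
#'   `torso_fluct_amp`, `cycle_duration`, `swing_peak_velocity`,
#'   `stance_residual_velocity`, `stance_duty`, plus `limb_reflectivities`
#'   and `label`.
#' @examples
#' p <- sample_class_params("elderly", rng_seed = 7)
#' p$torso_speed
#' @export
sample_class_params <- function(label, rng_seed,
                                config = gait_default_config(),
                                v_max = 0.98 * nyquist_velocity(radar_config())) {
  label <- check_gait_label(label)
  if (is.null(config[[label]])) {
    stop(sprintf("config has no section for class '%s'", label), call. = FALSE)
  }
  cc <- config[[label]]
  with_seed(rng_seed, {
    # The swing foot must clearly overtake the whole torso band (speed +
    # oscillation + two velocity bins) for the upper envelope to track it.
    # The torso window is capped so that a feasible swing value always
    # exists; because the cap enters a truncation window symmetric about the
    # mean, the torso draw stays unbiased. The swing draw is then taken from
    # the part of its own window that overtakes the realized torso, which
    # skews swing peaks slightly upward for fast walkers.
    swing_hi <- min(
      cc$swing_peak_velocity_mean + 2.5 * cc$swing_peak_velocity_sd, v_max
    )
    torso <- rtrunc_norm(cc$torso_speed_mean, cc$torso_speed_sd,
      cap = min(
        v_max - cc$torso_fluct_amp - 0.1,
        swing_hi - cc$torso_fluct_amp - 0.06
      )
    )
    cycle <- rtrunc_norm(cc$cycle_duration_mean, cc$cycle_duration_sd, cap = 3)
    swing <- rtrunc_norm(cc$swing_peak_velocity_mean, cc$swing_peak_velocity_sd,
      cap = v_max, floor = torso + cc$torso_fluct_amp + 0.06
    )
    structure(
      list(
        label = label,
        torso_speed = torso,
        torso_fluct_amp = cc$torso_fluct_amp,
        cycle_duration = cycle,
        swing_peak_velocity = swing,
        stance_residual_velocity = cc$stance_residual_velocity,
        stance_duty = cc$stance_duty,
        limb_reflectivities = cc$limb_reflectivities
      ),
      class = "gait_class_params"
    )
  })
}

# Normal draw truncated to a window symmetric about the mean:
# half-width = min(2.5 sd, cap - mean). Symmetry keeps the mean unbiased
# when the cap binds; positivity follows because mean > 2.5 sd in all
# shipped configurations. An optional hard floor (used to force the swing
# peak above the realized torso band) further truncates from below.
rtrunc_norm <- function(mean, sd, cap = Inf, floor = -Inf) {
  if (sd <= 0) {
    return(max(min(mean, cap), floor))
  }
  half <- min(2.5 * sd, cap - mean)
  if (half <= 0) {
    stop(sprintf("distribution mean %.3g exceeds cap %.3g", mean, cap), call. = FALSE)
  }
  lo <- max(mean - half, floor)
  hi <- mean + half
  if (lo >= hi) {
    return(hi)
  }
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) {
      return(x)
    }
  }
}

#' @export
print.gait_class_params <- function(x, ...) {
  cat(sprintf(
    "<gait_class_params> %s: torso %.3f m/s (fluct %.2f), cycle %.3f s, swing peak %.3f m/s, stance residual %.2f m/s\n",
    x$label, x$torso_speed, x$torso_fluct_amp, x$cycle_duration,
    x$swing_peak_velocity, x$stance_residual_velocity
  ))
  invisible(x)
}
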