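#' Simulate a labeled cohort of radar gait recordings
#'
#' Draws independent per-participant gait parameters from the class
#' configurations, simulates each walker, and synthesizes the complex
#' baseband echo. Per-participant seeds are derived deterministically from
#' `rng_seed`, so the same master seed reproduces the cohort bit for bit.
#'
#' @param n_young,n_elderly Number of participants per class (non-negative).
#' @param config Named list of [gait_class_config()] objects (default
#'   [gait_default_config()]).
#' @param radar A [radar_config()].
#' @param rng_seed Master integer seed.
#' @param n_cycles Gait cycles simulated per recording (default 5, so a
#'   steady-state two-cycle analysis interval fits comfortably inside).
#' @param noise_sd Additive complex-noise standard deviation per component
#'   passed to [synthesize_baseband()].
#' @param start_range Initial torso range (m).
#'
#' @return A tibble with one row per recording: `id`, `label`, `seed`, the
#'   realized parameter draw as columns (`torso_speed`, `cycle_duration`,
#'   `swing_peak_velocity`, `stance_residual_velocity`), and list-columns
#'   `params` and `signal`. Dropping `signal` and `params` gives the manifest
#'   (see [write_manifest()]).
#' @examples
#' ds <- make_dataset(3, 4, rng_seed = 1)
#' table(ds$label)
#' @export
make_dataset <- function(n_young, n_elderly,
                         config = gait_default_config(),
                         radar = radar_config(),
                         rng_seed = 1,
                         n_cycles = 5,
                         noise_sd = 0.05,
                         start_range = 9) {
  if (n_young < 0 || n_elderly < 0) stop("participant counts must be non-negative", call. = FALSE)
  labels <- rep(gait_labels(), times = c(n_young, n_elderly))
  n <- length(labels)
  if (n == 0L) {
    return(tibble::tibble(
      id = character(), label = factor(character(), levels = gait_labels()),
      seed = integer(), torso_speed = numeric(), cycle_duration = numeric(),
      swing_peak_velocity = numeric(), stance_residual_velocity = numeric(),
      params = list(), signal = list()
    ))
  }
  v_max <- 0.98 * nyquist_velocity(radar)
  rows <- purrr::map(seq_len(n), function(i) {
    seed_i <- derive_seed(rng_seed, i)
    params <- sample_class_params(labels[i], seed_i, config = config, v_max = v_max)
    traj <- simulate_walker(params,
      n_cycles = n_cycles, config = radar,
      start_range = start_range, rng_seed = derive_seed(seed_i, 1L)
    )
    sig <- synthesize_baseband(traj,
      config = radar, noise_sd = noise_sd,
      rng_seed = derive_seed(seed_i, 2L)
    )
    tibble::tibble(
      id = sprintf("%s_%03d", labels[i], i),
      label = factor(labels[i], levels = gait_labels()),
      seed = seed_i,
      torso_speed = params$torso_speed,
      cycle_duration = params$cycle_duration,
      swing_peak_velocity = params$swing_peak_velocity,
      stance_residual_velocity = params$stance_residual_velocity,
      params = list(params),
      signal = list(sig)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write / read a dataset manifest
#'
#' The manifest is the dataset tibble without its in-memory list-columns: one
#' CSV record per trial with id, label, seed, the realized parameter draw and
#' (when signals are written alongside) the signal file path.
#'
#' @param dataset A tibble from [make_dataset()].
#' @param dir Directory to write into (created if needed).
#' @param write_signals If `TRUE`, each baseband signal is also written as
#'   `signals/<id>.csv` via [write_baseband()] and the manifest records the
#'   relative path.
#' @return `write_manifest()` returns the manifest path invisibly;
#'   `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(dataset, dir, write_signals = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- dplyr::select(dataset, -dplyr::any_of(c("params", "signal")))
  if (write_signals && nrow(dataset) > 0L) {
    sig_dir <- file.path(dir, "signals")
    if (!dir.exists(sig_dir)) dir.create(sig_dir)
    manifest$signal_path <- file.path("signals", paste0(dataset$id, ".csv"))
    purrr::walk2(
      dataset$signal, manifest$signal_path,
      function(s, p) write_baseband(s, file.path(dir, p))
    )
  }
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @param path Path to a `manifest.csv`.
#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Extract envelope sequences for a whole dataset
#'
#' Runs the signal-processing chain — spectrogram, steady-state two-cycle
#' interval selection, envelope extraction — over every recording of a
#' dataset, producing the classifier-ready sequences.
#'
#' @param dataset A tibble from [make_dataset()] (columns `id`, `label`,
#'   `signal`).
#' @param radar A [radar_config()].
#' @param window_len,hop STFT parameters, see [compute_spectrogram()].
#' @param rho Peak threshold, see [extract_envelopes()].
#' @param n_cycles Gait cycles in the analysis interval (default 2).
#'
#' @return The dataset tibble with `signal` replaced by list-column
#'   `envelopes` (each an `envelope_set`) plus `n_frames` and the estimated
#'   `cycle_s`.
#' @examples
#' ds <- make_dataset(2, 2, rng_seed = 1)
#' prep <- prepare_sequences(ds)
#' range(prep$n_frames)
#' @export
prepare_sequences <- function(dataset, radar = radar_config(),
                              window_len = 128, hop = 8, rho = 0.2,
                              n_cycles = 2) {
  stopifnot(is.data.frame(dataset), all(c("id", "label", "signal") %in% names(dataset)))
  envs <- purrr::map(dataset$signal, function(sig) {
    sp <- compute_spectrogram(sig, window_len = window_len, hop = hop, config = radar)
    sp <- select_analysis_interval(sp, n_cycles = n_cycles)
    env <- suppressMessages(extract_envelopes(sp, rho = rho))
    env$cycle_s <- sp$cycle_estimate$cycle
    env
  })
  out <- dplyr::select(dataset, -dplyr::any_of(c("signal", "params")))
  out$envelopes <- envs
  out$n_frames <- vapply(envs, function(e) length(e$frame_times), integer(1))
  out$cycle_s <- vapply(envs, function(e) e$cycle_s, numeric(1))
  out
}

#' Build labeled classifier sequences for one input condition
#'
#' @param prepared A tibble from [prepare_sequences()].
#' @param condition Integer 1..7, see [condition_channels()].
#' @return A tibble with `id`, `label` and list-column `sequence`
#'   (frames x channels matrices), ready for [train_lstm()].
#' @export
condition_sequences <- function(prepared, condition) {
  stopifnot(is.data.frame(prepared), "envelopes" %in% names(prepared))
  tibble::tibble(
    id = prepared$id,
    label = prepared$label,
    sequence = purrr::map(prepared$envelopes, build_condition_input, condition = condition)
  )
}
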