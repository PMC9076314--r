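#' @keywords internal
"_PACKAGE"

#' Default movement label set
#'
#' Ten finger movements: five individual (thumb, index, middle, ring, little)
#' and five combined (thumb-index, thumb-middle, thumb-ring, thumb-little,
#' hand closing).
#'
#' @return Character vector of ten movement codes.
#' @export
default_movements <- function() {
  c("T", "I", "M", "R", "L", "TI", "TM", "TR", "TL", "HC")
}

#' Default per-movement, per-channel amplitude table
#'
#' Each movement carries a distinct two-channel amplitude signature so that
#' classes are separable by amplitude pattern, mirroring steady-state forearm
#' recordings where amplitude is the dominant distinguishing property. Two
#' movements ("R" and "L") are deliberately weak -- their amplitudes sit close
#' to the default noise floor -- to emulate movements with weak signal
#' strengths.
#'
#' @param movements character vector of movement labels.
#' @param n_channels number of channels.
#' @return Numeric matrix `[n_movements x n_channels]` with movement rownames.
#' @export
default_amplitudes <- function(movements = default_movements(), n_channels = 2) {
  base <- matrix(
    c(
      1.00, 0.30, # T: strong flexor
      0.60, 0.80, # I
      0.45, 1.10, # M
      0.10, 0.16, # R: weak
      0.16, 0.10, # L: weak
      1.30, 0.70, # TI
      0.90, 1.30, # TM
      0.70, 0.45, # TR
      0.35, 0.60, # TL
      1.60, 1.60  # HC: strong co-contraction
    ),
    ncol = 2, byrow = TRUE
  )
  n <- length(movements)
  amp <- matrix(0, n, n_channels, dimnames = list(movements, NULL))
  for (k in seq_len(n_channels)) {
    amp[, k] <- base[((seq_len(n) - 1L) %% nrow(base)) + 1L, ((k - 1L) %% 2L) + 1L]
  }
  amp
}

#' Synthetic EMG dataset configuration
#'
#' Describes a multi-movement, multi-trial steady-state surface-EMG recording
#' session: each trial of each movement is band-limited Gaussian noise (the
#' carrier) scaled by the movement's per-channel amplitude, plus additive
#' white Gaussian measurement noise.
#'
#' @param n_channels number of electrode channels (default 2).
#' @param movements character vector of movement labels (default the ten
#'   finger movements of [default_movements()]).
#' @param n_trials trials per movement (default 6).
#' @param duration_s trial duration in seconds (default 5).
#' @param fs sampling rate in Hz (default 2000).
#' @param amplitudes numeric matrix `[n_movements x n_channels]` of
#'   non-negative carrier amplitudes (default [default_amplitudes()]).
#' @param band two-element numeric, carrier band edges in Hz (default
#'   `c(20, 500)`).
#' @param noise_rms RMS of the additive white Gaussian noise floor, same units
#'   as the amplitudes (default 0.1, placing O(1)-amplitude movements in the
#'   5--23 dB SNR range typical of wet-electrode recordings).
#' @param force_jitter_sd standard deviation, on the log scale, of a slow
#'   multiplicative envelope modulation applied to the physiological carrier
#'   (not the electrode noise), emulating force fluctuation during a held
#'   contraction. Default 0: perfectly constant steady-state envelopes.
#' @param force_jitter_hz bandwidth (Hz) of the modulation when
#'   `force_jitter_sd > 0` (default 2, a slow force-tremor scale).
#' @param seed master integer seed; per-trial streams are derived from it by
#'   counter so one trial can be regenerated without perturbing the rest.
#' @param subject_id subject identifier string.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 2,
                         movements = default_movements(),
                         n_trials = 6,
                         duration_s = 5,
                         fs = 2000,
                         amplitudes = NULL,
                         band = c(20, 500),
                         noise_rms = 0.1,
                         force_jitter_sd = 0,
                         force_jitter_hz = 2,
                         seed = 1L,
                         subject_id = "synth01") {
  if (is.null(amplitudes)) {
    amplitudes <- default_amplitudes(movements, n_channels)
  }
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != length(movements) || ncol(amplitudes) != n_channels) {
    stop("`amplitudes` must be a [n_movements x n_channels] matrix", call. = FALSE)
  }
  if (any(amplitudes < 0) || any(!is.finite(amplitudes))) {
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  }
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("carrier band must satisfy low < high", call. = FALSE)
  }
  if (band[2] >= fs / 2) {
    stop("carrier band upper edge must lie below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  if (noise_rms < 0) stop("noise_rms must be non-negative", call. = FALSE)
  if (force_jitter_sd < 0) stop("force_jitter_sd must be non-negative",
                                call. = FALSE)
  rownames(amplitudes) <- movements
  structure(
    list(
      n_channels = as.integer(n_channels), movements = movements,
      n_trials = as.integer(n_trials), duration_s = duration_s, fs = fs,
      amplitudes = amplitudes, band = band, noise_rms = noise_rms,
      force_jitter_sd = force_jitter_sd, force_jitter_hz = force_jitter_hz,
      seed = as.integer(seed), subject_id = subject_id
    ),
    class = "synth_config"
  )
}

#' One labelled EMG trial
#'
#' @param samples numeric matrix `[n_samples x n_channels]`.
#' @param fs sampling rate, Hz.
#' @param movement movement label.
#' @param trial_index 1-based trial number.
#' @param subject_id subject identifier.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(samples, fs, movement, trial_index = 1L,
                            subject_id = "unknown") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, movement = as.character(movement),
         trial_index = as.integer(trial_index), subject_id = subject_id),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s trial %d (%s): %d samples x %d ch @ %g Hz\n",
              x$movement, x$trial_index, x$subject_id,
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

# Deterministic per-trial seed stream derived from the master seed by counter.
trial_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 16807) %% 2147483647)
}

#' Generate a synthetic EMG dataset
#'
#' Each channel of each trial is white Gaussian noise passed through the same
#' zero-phase Butterworth band-pass used by [emg_bandpass()], standardized to
#' unit RMS and scaled by the movement's channel amplitude, plus white
#' Gaussian noise of RMS `noise_rms`. When `force_jitter_sd > 0` the carrier
#' is additionally multiplied by a slow lognormal envelope (band-limited to
#' `force_jitter_hz`), giving amplitude features the multiplicative
#' within-class variability of a real held contraction. Deterministic for a
#' fixed config seed.
#'
#' @param config a [synth_config()].
#' @return List of [trial_recording()] objects, one per (movement, trial),
#'   ordered movement-major.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration_s * config$fs)
  flt <- butter_bandpass(config$band[1], config$band[2], config$fs)
  out <- vector("list", length(config$movements) * config$n_trials)
  counter <- 0L
  idx <- 1L
  for (mv in config$movements) {
    amp <- config$amplitudes[mv, ]
    for (tr in seq_len(config$n_trials)) {
      counter <- counter + 1L
      set.seed(trial_seed(config$seed, counter))
      x <- matrix(0, n, config$n_channels)
      for (ch in seq_len(config$n_channels)) {
        if (amp[ch] > 0) {
          carrier <- signal::filtfilt(flt, stats::rnorm(n))
          carrier <- carrier / sqrt(mean(carrier^2))
          if (config$force_jitter_sd > 0) {
            lp <- signal::butter(2, config$force_jitter_hz / (config$fs / 2),
                                 type = "low")
            g <- signal::filtfilt(lp, stats::rnorm(n))
            g <- g / stats::sd(g) * config$force_jitter_sd
            carrier <- carrier * exp(g)
          }
          x[, ch] <- amp[ch] * carrier
        }
        if (config$noise_rms > 0) {
          x[, ch] <- x[, ch] + stats::rnorm(n, sd = config$noise_rms)
        }
      }
      out[[idx]] <- trial_recording(x, config$fs, mv, tr, config$subject_id)
      idx <- idx + 1L
    }
  }
  out
}

#' Write a trial to delimited text with a JSON metadata sidecar
#'
#' Samples go to `path` as headerless CSV (one row per sample, one column per
#' channel); sampling rate, movement label, trial index and subject id go to
#' `<path>.json`.
#'
#' @param rec a [trial_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  utils::write.table(format(rec$samples, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = rec$fs, movement = rec$movement,
               trial_index = rec$trial_index, subject_id = rec$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial from delimited text
#'
#' Dialect-tolerant: accepts comma-, tab- or whitespace-separated numeric
#' text. Metadata comes from the JSON sidecar written by [write_trial()] when
#' present, otherwise from the `fs`/`movement`/... arguments.
#'
#' @param path input file path.
#' @param fs sampling rate (used when no sidecar exists).
#' @param movement,trial_index,subject_id metadata fallbacks.
#' @param n_channels if given, the file must have exactly this many columns.
#' @return A [trial_recording()].
#' @export
read_trial <- function(path, fs = NULL, movement = NULL, trial_index = 1L,
                       subject_id = "unknown", n_channels = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty trial file: ", path, call. = FALSE)
  parsed <- lapply(lines, function(l) {
    strsplit(trimws(l), "[,\t ]+")[[1]]
  })
  ncol1 <- length(parsed[[1]])
  for (i in seq_along(parsed)) {
    if (length(parsed[[i]]) != ncol1) {
      stop(sprintf("parse error in %s at line %d: %d fields, expected %d",
                   path, i, length(parsed[[i]]), ncol1), call. = FALSE)
    }
  }
  if (!is.null(n_channels) && ncol1 != n_channels) {
    stop(sprintf("channel-count mismatch in %s: file has %d columns, expected %d",
                 path, ncol1, n_channels), call. = FALSE)
  }
  num <- suppressWarnings(vapply(parsed, as.numeric, numeric(ncol1)))
  mat <- if (ncol1 == 1) matrix(num, ncol = 1) else t(num)
  if (anyNA(mat)) {
    bad <- which(apply(if (ncol1 == 1) is.na(mat) else is.na(mat), 1, any))[1]
    stop(sprintf("parse error in %s at line %d: non-numeric cell", path, bad),
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- meta$fs
    movement <- meta$movement
    trial_index <- meta$trial_index
    subject_id <- meta$subject_id
  }
  if (is.null(fs)) stop("fs must be supplied when no metadata sidecar exists",
                        call. = FALSE)
  if (is.null(movement)) movement <- "unknown"
  trial_recording(mat, fs, movement, trial_index, subject_id)
}

#' Write a whole dataset under `dir/<subject>/<movement>_<trial>.csv`
#'
#' @param dataset list of [trial_recording()].
#' @param dir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  paths <- character(length(dataset))
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    sub <- file.path(dir, rec$subject_id)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, sprintf("%s_%d.csv", rec$movement, rec$trial_index))
    write_trial(rec, paths[i])
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset root directory.
#' @return List of [trial_recording()].
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no trial files under ", dir, call. = FALSE)
  lapply(files, read_trial)
}
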