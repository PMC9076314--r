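# Butterworth band-pass shared by the generator and the preprocessing front
# end: order 2 per edge (4th-order band-pass), applied forward-backward.
butter_bandpass <- function(low_hz, high_hz, fs) {
  if (low_hz >= high_hz) stop("band-pass requires low < high", call. = FALSE)
  if (high_hz >= fs / 2) {
    stop("band-pass upper edge must lie below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# RBJ cookbook biquad notch at f0 with quality factor Q.
notch_biquad <- function(f0_hz, fs, Q = 30) {
  if (f0_hz >= fs / 2) {
    stop("notch frequency must lie below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  w0 <- 2 * pi * f0_hz / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

apply_filter_rec <- function(rec, flt) {
  y <- rec$samples
  for (ch in seq_len(ncol(y))) {
    y[, ch] <- signal::filtfilt(flt, rec$samples[, ch])
  }
  out <- rec
  out$samples <- y
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass (default 20--500 Hz) applied
#' forward-backward per channel, so the output has no phase distortion and the
#' effective magnitude response is squared.
#'
#' @param rec a [trial_recording()].
#' @param low_hz,high_hz band edges in Hz.
#' @return Filtered [trial_recording()], same shape.
#' @export
emg_bandpass <- function(rec, low_hz = 20, high_hz = 500) {
  stopifnot(inherits(rec, "trial_recording"))
  apply_filter_rec(rec, butter_bandpass(low_hz, high_hz, rec$fs))
}

#' Zero-phase power-line notch filter
#'
#' Second-order IIR notch (quality factor 30) at `f0_hz`, applied
#' forward-backward per channel. Narrow enough to leave a tone 50 Hz away
#' essentially untouched.
#'
#' @param rec a [trial_recording()].
#' @param f0_hz notch centre frequency in Hz (default 50, European mains).
#' @param Q quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered [trial_recording()], same shape.
#' @export
emg_notch <- function(rec, f0_hz = 50, Q = 30) {
  stopifnot(inherits(rec, "trial_recording"))
  apply_filter_rec(rec, notch_biquad(f0_hz, rec$fs, Q))
}

#' Disjoint windowing of a trial
#'
#' Splits the trial into `floor(n_samples / window_len)` contiguous,
#' non-overlapping windows anchored at sample 1; any trailing remainder is
#' discarded. A 5 s trial at 2000 Hz with 250 ms windows yields exactly 20
#' segments of 500 samples.
#'
#' @param rec a [trial_recording()].
#' @param window_ms window length in milliseconds.
#' @return List of window segments; each has `samples`
#'   (`[window_len x n_channels]`), `window_ms`, `window_index` (0-based),
#'   `movement`, `trial_index`, `subject_id`, `fs`.
#' @export
segment_disjoint <- function(rec, window_ms = 250) {
  stopifnot(inherits(rec, "trial_recording"))
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  wl <- round(window_ms / 1000 * rec$fs)
  n <- nrow(rec$samples)
  if (wl > n) stop("window longer than trial", call. = FALSE)
  k <- floor(n / wl)
  lapply(seq_len(k) - 1L, function(i) {
    structure(
      list(samples = rec$samples[(i * wl + 1L):((i + 1L) * wl), , drop = FALSE],
           window_ms = window_ms, window_index = i, movement = rec$movement,
           trial_index = rec$trial_index, subject_id = rec$subject_id,
           fs = rec$fs),
      class = "window_segment"
    )
  })
}

#' Signal-to-noise ratio in dB from raw and noise RMS
#'
#' The noise power is subtracted from the raw (signal + noise) power before
#' forming the ratio: `20 log10( sqrt(raw_rms^2 - noise_rms^2) / noise_rms )`.
#'
#' @param raw_rms RMS of the recorded (signal + noise) trace.
#' @param noise_rms RMS of the noise-only (rest) trace; must be positive and
#'   strictly smaller than `raw_rms`.
#' @return SNR in dB.
#' @export
snr_db <- function(raw_rms, noise_rms) {
  if (any(noise_rms <= 0)) stop("noise_rms must be positive", call. = FALSE)
  if (any(raw_rms <= noise_rms)) {
    stop("raw_rms must exceed noise_rms (no real signal component otherwise)",
         call. = FALSE)
  }
  20 * log10(sqrt(raw_rms^2 - noise_rms^2) / noise_rms)
}

#' Contaminate a trial with additive white Gaussian noise at a target SNR
#'
#' Measures the signal power per channel and adds zero-mean Gaussian noise
#' with power `signal_power / 10^(snr_db/10)` (the semantics of measuring the
#' input power before mixing). Deterministic for a fixed seed.
#'
#' @param rec a [trial_recording()].
#' @param snr target signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @return Contaminated [trial_recording()].
#' @export
add_awgn <- function(rec, snr, seed = 1L) {
  stopifnot(inherits(rec, "trial_recording"))
  set.seed(as.integer(seed))
  y <- rec$samples
  for (ch in seq_len(ncol(y))) {
    p_sig <- mean(y[, ch]^2)
    if (p_sig <= 0) stop("cannot add noise at a target SNR to a zero-power channel",
                         call. = FALSE)
    sd_n <- sqrt(p_sig / 10^(snr / 10))
    y[, ch] <- y[, ch] + stats::rnorm(nrow(y), sd = sd_n)
  }
  out <- rec
  out$samples <- y
  out
}

#' Standard digital preprocessing front end
#'
#' Band-pass (20--500 Hz) then power-line notch (50 Hz), both zero-phase,
#' applied to the whole trial before any segmentation so windows carry no
#' per-window filter transients.
#'
#' @param rec a [trial_recording()].
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param notch_hz notch centre in Hz; `NA` disables the notch.
#' @return Filtered [trial_recording()].
#' @export
preprocess_trial <- function(rec, low_hz = 20, high_hz = 500, notch_hz = 50) {
  out <- emg_bandpass(rec, low_hz, high_hz)
  if (!is.na(notch_hz)) out <- emg_notch(out, notch_hz)
  out
}
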