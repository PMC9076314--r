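# Zero-guard applied inside logarithms so degenerate (all-zero or constant)
# windows stay finite and downstream scatter matrices stay well-posed.
.log_eps <- 1e-12

check_window <- function(x, min_n = 1, feature = "feature") {
  if (!is.numeric(x) || length(x) < min_n) {
    stop(sprintf("%s requires a numeric window of at least %d samples",
                 feature, min_n), call. = FALSE)
  }
  invisible(length(x))
}

#' Log mean absolute value (LMAV)
#'
#' Natural logarithm of the window's mean rectified amplitude,
#' `ln( (1/N) sum |x_i| )`. The log compresses dynamic range, so differences
#' between weak contractions are magnified relative to differences between
#' strong ones. An internal floor of `1e-12` keeps all-zero windows finite.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @return Scalar feature value.
#' @export
lmav <- function(x) {
  check_window(x, 1, "lmav")
  log(max(.log_eps, mean(abs(x))))
}

#' Nonlinear scaled value (NSV)
#'
#' With `xbar` the window's mean absolute value, returns
#' `ln( (1/N) sum ( (xbar - x_i)^(1/3) )^2 )`, where the cube root is the real
#' signed cube root, so each term equals `|xbar - x_i|^(2/3)`. The fractional
#' power emphasizes small deviations of each sample from the window's linear
#' amplitude level, targeting weak contractions. Floored at `1e-12` inside the
#' log for degenerate (constant) windows.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @param rectify if `TRUE`, deviations are taken from the rectified samples
#'   `|x_i|` instead of the raw samples (default `FALSE`).
#' @return Scalar feature value.
#' @export
nsv <- function(x, rectify = FALSE) {
  check_window(x, 1, "nsv")
  xbar <- mean(abs(x))
  xi <- if (rectify) abs(x) else x
  log(max(.log_eps, mean(abs(xbar - xi)^(2 / 3))))
}

#' Classical time-domain EMG features
#'
#' Single-channel window statistics from the standard myoelectric feature
#' inventory:
#' \describe{
#'   \item{`mav`}{mean absolute value `(1/N) sum |x_i|`.}
#'   \item{`iemg`}{integrated EMG `sum |x_i|`.}
#'   \item{`emg_rms`}{root mean square.}
#'   \item{`emg_var`}{sample variance with `N-1` denominator.}
#'   \item{`ssi`}{simple square integral `sum x_i^2`.}
#'   \item{`wl`}{waveform length `sum |x_{i+1} - x_i|`.}
#'   \item{`zc`}{zero crossings: sign changes whose jump `|x_{i+1} - x_i|`
#'     meets the threshold.}
#'   \item{`ssc`}{slope sign changes: interior samples where consecutive
#'     slopes have opposite sign and the larger slope magnitude meets the
#'     threshold.}
#'   \item{`wamp`}{Wilson amplitude: count of `|x_{i+1} - x_i| >= thr`.}
#'   \item{`myop`}{myopulse percentage rate: fraction of `|x_i| >= thr`.}
#'   \item{`log_detector`}{`exp( (1/N) sum ln |x_i| )` (geometric mean of the
#'     rectified signal, floored at 1e-12).}
#'   \item{`damv`}{difference absolute mean value `mean |diff(x)|`.}
#'   \item{`dasdv`}{difference absolute standard deviation value
#'     `sqrt(mean diff(x)^2)`.}
#'   \item{`skw`}{central-moment skewness `m3 / m2^(3/2)` (0 for constant
#'     windows).}
#'   \item{`kurt`}{excess kurtosis `m4 / m2^2 - 3` (0 for constant windows).}
#'   \item{`mob`}{Hjorth mobility `sqrt(var(diff(x)) / var(x))`.}
#'   \item{`com`}{Hjorth complexity `mob(diff(x)) / mob(x)`.}
#'   \item{`mfl`}{maximum fractal length `log10 sqrt(sum diff(x)^2)`.}
#' }
#' Degenerate denominators (constant windows) return 0 rather than NaN so
#' feature matrices stay finite.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @param thr amplitude threshold (same units as the signal) for `zc`, `ssc`,
#'   `wamp`, `myop`.
#' @return Scalar feature value.
#' @name classical_features
NULL

#' @rdname classical_features
#' @export
mav <- function(x) {
  check_window(x, 1, "mav")
  mean(abs(x))
}

#' @rdname classical_features
#' @export
iemg <- function(x) {
  check_window(x, 1, "iemg")
  sum(abs(x))
}

#' @rdname classical_features
#' @export
emg_rms <- function(x) {
  check_window(x, 1, "emg_rms")
  sqrt(mean(x^2))
}

#' @rdname classical_features
#' @export
emg_var <- function(x) {
  check_window(x, 2, "emg_var")
  stats::var(x)
}

#' @rdname classical_features
#' @export
ssi <- function(x) {
  check_window(x, 1, "ssi")
  sum(x^2)
}

#' @rdname classical_features
#' @export
wl <- function(x) {
  check_window(x, 2, "wl")
  sum(abs(diff(x)))
}

#' @rdname classical_features
#' @export
zc <- function(x, thr = 0) {
  check_window(x, 2, "zc")
  d <- abs(diff(x))
  s <- x[-length(x)] * x[-1]
  sum(s < 0 & d >= thr)
}

#' @rdname classical_features
#' @export
ssc <- function(x, thr = 0) {
  check_window(x, 3, "ssc")
  n <- length(x)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= thr)
}

#' @rdname classical_features
#' @export
wamp <- function(x, thr = 0.01) {
  check_window(x, 2, "wamp")
  sum(abs(diff(x)) >= thr)
}

#' @rdname classical_features
#' @export
myop <- function(x, thr = 0.016) {
  check_window(x, 1, "myop")
  mean(abs(x) >= thr)
}

#' @rdname classical_features
#' @export
log_detector <- function(x) {
  check_window(x, 1, "log_detector")
  exp(mean(log(pmax(.log_eps, abs(x)))))
}

#' @rdname classical_features
#' @export
damv <- function(x) {
  check_window(x, 2, "damv")
  mean(abs(diff(x)))
}

#' @rdname classical_features
#' @export
dasdv <- function(x) {
  check_window(x, 2, "dasdv")
  sqrt(mean(diff(x)^2))
}

#' @rdname classical_features
#' @export
skw <- function(x) {
  check_window(x, 2, "skw")
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

#' @rdname classical_features
#' @export
kurt <- function(x) {
  check_window(x, 2, "kurt")
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' @rdname classical_features
#' @export
mob <- function(x) {
  check_window(x, 3, "mob")
  v0 <- stats::var(x)
  if (v0 <= 0) return(0)
  sqrt(stats::var(diff(x)) / v0)
}

#' @rdname classical_features
#' @export
com <- function(x) {
  check_window(x, 4, "com")
  m0 <- mob(x)
  if (m0 <= 0) return(0)
  mob(diff(x)) / m0
}

#' @rdname classical_features
#' @export
mfl <- function(x) {
  check_window(x, 2, "mfl")
  log10(max(.log_eps, sqrt(sum(diff(x)^2))))
}

#' Autoregressive coefficients by Yule-Walker estimation
#'
#' Coefficients `a_k` of the linear prediction `x_i ~ sum_k a_k x_{i-k}`,
#' estimated from the autocorrelation (Yule-Walker) equations. A constant or
#' zero window returns all-zero coefficients.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @param order model order (default 4).
#' @return Numeric vector of `order` coefficients.
#' @export
ar_coeffs <- function(x, order = 4) {
  check_window(x, order + 1, "ar_coeffs")
  if (stats::var(x) <= .log_eps^2) return(rep(0, order))
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker",
                   demean = TRUE)
  a <- fit$ar
  if (length(a) < order) a <- c(a, rep(0, order - length(a)))
  a
}

# Time-domain surrogates for spectral moments: m0 from the signal energy, m2
# from first differences, m4 from second differences (root-squared form).
spectral_moments <- function(x) {
  d1 <- diff(x)
  d2 <- diff(d1)
  c(m0 = sqrt(sum(x^2)), m2 = sqrt(sum(d1^2)), m4 = sqrt(sum(d2^2)))
}

#' Irregularity factor and sparseness from time-domain spectral moments
#'
#' With root-squared moment surrogates `m0 = sqrt(sum x^2)`,
#' `m2 = sqrt(sum (dx)^2)`, `m4 = sqrt(sum (d2x)^2)`: the irregularity factor
#' is `m2 / sqrt(m0 m4)` (1 in the narrowband single-line limit) and
#' sparseness is `m0 / sqrt(|(m0 - m2)(m0 - m4)|)`. Both are ratios of
#' homogeneous moment surrogates, hence invariant to amplitude scaling.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @return Scalar.
#' @name moment_ratios
NULL

#' @rdname moment_ratios
#' @export
irregularity_factor <- function(x) {
  check_window(x, 3, "irregularity_factor")
  m <- spectral_moments(x)
  if (m["m0"] <= 0 || m["m4"] <= 0) stop("zero-energy window", call. = FALSE)
  unname(m["m2"] / sqrt(m["m0"] * m["m4"]))
}

#' @rdname moment_ratios
#' @export
sparseness <- function(x) {
  check_window(x, 3, "sparseness")
  m <- spectral_moments(x)
  den <- sqrt(abs((m["m0"] - m["m2"]) * (m["m0"] - m["m4"])))
  if (den <= 0) stop("degenerate moments", call. = FALSE)
  unname(m["m0"] / den)
}

#' Time-dependent power-spectrum descriptors (6 features)
#'
#' Six log-scaled descriptors built from the time-domain moment surrogates of
#' [spectral moments][irregularity_factor]: the power-transformed zero-order
#' moment and the two moment differences (`m^lambda / lambda`,
#' `lambda = 0.1`), log sparseness, log irregularity factor, and the log
#' waveform-length ratio `sum|dx| / sum|d2x|`. Sparseness and irregularity are
#' computed from the raw (untransformed) moments so they remain exactly
#' scale-invariant.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @param lambda power-transform exponent for the moment magnitudes.
#' @return Named numeric vector of 6 descriptors.
#' @export
tdpsd_features <- function(x, lambda = 0.1) {
  check_window(x, 3, "tdpsd_features")
  m <- spectral_moments(x)
  if (m["m0"] <= 0) stop("zero-energy window", call. = FALSE)
  pt <- function(v) (max(.log_eps, abs(v)))^lambda / lambda
  d1 <- diff(x)
  d2 <- diff(d1)
  c(
    tm0   = log(pt(m["m0"])),
    tm0m2 = log(pt(m["m0"] - m["m2"])),
    tm0m4 = log(pt(m["m0"] - m["m4"])),
    tspars = log(max(.log_eps, sparseness(x))),
    tirf  = log(max(.log_eps, irregularity_factor(x))),
    twlr  = log(max(.log_eps, sum(abs(d1)) / max(.log_eps, sum(abs(d2)))))
  )
}

#' Coefficient of variation of the rectified signal
#'
#' `sd(|x|) / mean(|x|)`. The rectified form is used because raw surface EMG
#' is zero-mean, which makes the usual `sd/mean` ratio unstable.
#'
#' @param x numeric vector, one channel of one analysis window.
#' @return Scalar.
#' @export
cov_rect <- function(x) {
  check_window(x, 2, "cov_rect")
  m <- mean(abs(x))
  if (m <= 0) return(0)
  stats::sd(abs(x)) / m
}

#' Log Teager-Kaiser energy
#'
#' `ln( mean |x_i^2 - x_{i-1} x_{i+1}| )` over interior samples, floored at
#' 1e-12; an instantaneous energy operator sensitive to both amplitude and
#' frequency (the absolute value keeps noisy windows, whose raw operator mean
#' can cross zero, well-defined).
#'
#' @param x numeric vector, one channel of one analysis window.
#' @return Scalar.
#' @export
tkeo <- function(x) {
  check_window(x, 3, "tkeo")
  n <- length(x)
  psi <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  log(max(.log_eps, mean(abs(psi))))
}

#' Temporal-spatial descriptors (7 features)
#'
#' Seven descriptors per channel: the three power-transformed moment
#' magnitudes and log sparseness / log irregularity factor as in
#' [tdpsd_features()], plus the log coefficient of variation of the rectified
#' signal and the log Teager-Kaiser energy.
#'
#' @inheritParams tdpsd_features
#' @return Named numeric vector of 7 descriptors.
#' @export
tsd_features <- function(x, lambda = 0.1) {
  check_window(x, 3, "tsd_features")
  td <- tdpsd_features(x, lambda)
  c(td[c("tm0", "tm0m2", "tm0m4", "tspars", "tirf")],
    tcov = log(max(.log_eps, cov_rect(x))),
    ttkeo = tkeo(x))
}
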