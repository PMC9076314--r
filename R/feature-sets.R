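# Registry of scalar feature extractors. Multi-output entries (AR, TD-PSD,
# TSD) are expanded into individually named columns by the evaluators below.
feature_registry <- function(params = feature_params()) {
  thr <- params
  list(
    MAV  = function(x) mav(x),
    IEMG = function(x) iemg(x),
    RMS  = function(x) emg_rms(x),
    VAR  = function(x) emg_var(x),
    SSI  = function(x) ssi(x),
    WL   = function(x) wl(x),
    ZC   = function(x) zc(x, thr$zc_thr),
    SSC  = function(x) ssc(x, thr$ssc_thr),
    WAMP = function(x) wamp(x, thr$wamp_thr),
    MYOP = function(x) myop(x, thr$myop_thr),
    LOG  = function(x) log_detector(x),
    DAMV = function(x) damv(x),
    DASDV = function(x) dasdv(x),
    SKW  = function(x) skw(x),
    KURT = function(x) kurt(x),
    MOB  = function(x) mob(x),
    COM  = function(x) com(x),
    MFL  = function(x) mfl(x),
    LMAV = function(x) lmav(x),
    NSV  = function(x) nsv(x, thr$nsv_rectify),
    COV  = function(x) cov_rect(x),
    TKEO = function(x) tkeo(x)
  )
}

#' Per-feature threshold and order parameters
#'
#' Defaults: zero-crossing and slope-sign-change thresholds 0, Wilson
#' amplitude threshold 0.01 (10 mV-equivalent in volt units), myopulse
#' threshold 0.016, AR order 4 (6 in the FS1 baseline), power-transform
#' exponent 0.1 for the moment descriptors.
#'
#' @param zc_thr,ssc_thr,wamp_thr,myop_thr amplitude thresholds.
#' @param ar_order autoregressive model order for `AR1..ARk` columns.
#' @param lambda power-transform exponent for TD-PSD/TSD moments.
#' @param nsv_rectify pass `rectify = TRUE` to [nsv()].
#' @return Named list of parameters.
#' @export
feature_params <- function(zc_thr = 0, ssc_thr = 0, wamp_thr = 0.01,
                           myop_thr = 0.016, ar_order = 4, lambda = 0.1,
                           nsv_rectify = FALSE) {
  list(zc_thr = zc_thr, ssc_thr = ssc_thr, wamp_thr = wamp_thr,
       myop_thr = myop_thr, ar_order = ar_order, lambda = lambda,
       nsv_rectify = nsv_rectify)
}

#' Feature-set specification
#'
#' Named baseline sets per channel:
#' \describe{
#'   \item{`FS1`}{6 autoregressive coefficients + RMS (7 features).}
#'   \item{`FS2`}{IEMG, WL, WAMP, ZC, SSC, VAR (6 features).}
#'   \item{`FS3`}{the 6 time-dependent power-spectrum descriptors.}
#'   \item{`FS4`}{the 7 temporal-spatial descriptors.}
#'   \item{`PROPOSED`}{LMAV, NSV, WL, WAMP, SSC, ZC, MOB, COM, SKW, AR1--AR4
#'     (13 features).}
#' }
#' A custom set is any vector of registry names (`AR1..ARk`, `TDPSD`, `TSD`
#' are understood).
#'
#' @param name one of `"FS1"`, `"FS2"`, `"FS3"`, `"FS4"`, `"PROPOSED"`, or
#'   `"custom"`.
#' @param features for `name = "custom"`, the ordered feature names.
#' @param params a [feature_params()] list.
#' @return Object of class `feature_set` with elements `name`, `features`,
#'   `params`.
#' @export
feature_set <- function(name = c("PROPOSED", "FS1", "FS2", "FS3", "FS4", "custom"),
                        features = NULL, params = feature_params()) {
  name <- match.arg(name)
  feats <- switch(name,
    FS1 = c(paste0("AR", 1:6), "RMS"),
    FS2 = c("IEMG", "WL", "WAMP", "ZC", "SSC", "VAR"),
    FS3 = "TDPSD",
    FS4 = "TSD",
    PROPOSED = c("LMAV", "NSV", "WL", "WAMP", "SSC", "ZC", "MOB", "COM",
                 "SKW", paste0("AR", 1:4)),
    custom = features
  )
  if (is.null(feats) || length(feats) == 0) {
    stop("custom feature set needs a non-empty `features` vector", call. = FALSE)
  }
  structure(list(name = name, features = feats, params = params),
            class = "feature_set")
}

#' Number of scalar features per channel in a feature set
#'
#' @param spec a [feature_set()].
#' @return Integer count after expanding AR/TD-PSD/TSD blocks.
#' @export
n_features_per_channel <- function(spec) {
  length(expand_feature_names(spec$features))
}

expand_feature_names <- function(features) {
  out <- character(0)
  for (f in features) {
    out <- c(out, switch(f,
      TDPSD = c("TM0", "TM0M2", "TM0M4", "TSPARS", "TIRF", "TWLR"),
      TSD = c("TM0", "TM0M2", "TM0M4", "TSPARS", "TIRF", "TCOV", "TTKEO"),
      f))
  }
  out
}

# Evaluate one channel window against an ordered feature-name list, expanding
# AR1..ARk / TDPSD / TSD blocks. Returns a named numeric vector.
eval_features_channel <- function(x, features, params) {
  reg <- feature_registry(params)
  vals <- numeric(0)
  ar_cache <- NULL
  ar_idx <- grep("^AR[0-9]+$", features, value = TRUE)
  if (length(ar_idx)) {
    ord <- max(as.integer(sub("^AR", "", ar_idx)))
    ar_cache <- ar_coeffs(x, ord)
  }
  for (f in features) {
    if (grepl("^AR[0-9]+$", f)) {
      k <- as.integer(sub("^AR", "", f))
      v <- ar_cache[k]
      names(v) <- f
    } else if (f == "TDPSD") {
      v <- tdpsd_features(x, params$lambda)
      names(v) <- c("TM0", "TM0M2", "TM0M4", "TSPARS", "TIRF", "TWLR")
    } else if (f == "TSD") {
      v <- tsd_features(x, params$lambda)
      names(v) <- c("TM0", "TM0M2", "TM0M4", "TSPARS", "TIRF", "TCOV", "TTKEO")
    } else {
      fn <- reg[[f]]
      if (is.null(fn)) stop("unknown feature: ", f, call. = FALSE)
      v <- fn(x)
      names(v) <- f
    }
    vals <- c(vals, v)
  }
  vals
}

#' Extract a feature matrix from window segments
#'
#' Computes every feature of `spec` per channel and concatenates channels, so
#' a 13-feature set on 2 channels yields 26 feature columns named
#' `<FEATURE>_ch<k>`. Window provenance (movement label, trial index, window
#' index) is carried in metadata columns.
#'
#' @param windows list of window segments from [segment_disjoint()].
#' @param spec a [feature_set()].
#' @return A `data.frame` of class `feature_matrix` with one row per window:
#'   feature columns (attribute `"feature_cols"`), plus `label`, `trial`,
#'   `window_index`, `subject`.
#' @export
extract_features <- function(windows, spec = feature_set("PROPOSED")) {
  stopifnot(inherits(spec, "feature_set"), length(windows) > 0)
  n_ch <- ncol(windows[[1]]$samples)
  wlen <- nrow(windows[[1]]$samples)
  fnames <- expand_feature_names(spec$features)
  cols <- as.vector(outer(fnames, seq_len(n_ch),
                          function(f, k) paste0(f, "_ch", k)))
  mat <- matrix(NA_real_, length(windows), length(cols),
                dimnames = list(NULL, cols))
  meta <- data.frame(label = character(length(windows)),
                     trial = integer(length(windows)),
                     window_index = integer(length(windows)),
                     subject = character(length(windows)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (ncol(w$samples) != n_ch || nrow(w$samples) != wlen) {
      stop("all windows must share length and channel count", call. = FALSE)
    }
    row <- numeric(0)
    for (ch in seq_len(n_ch)) {
      row <- c(row, eval_features_channel(w$samples[, ch], spec$features,
                                          spec$params))
    }
    if (any(!is.finite(row))) {
      bad <- cols[which(!is.finite(row))[1]]
      stop(sprintf("non-finite feature %s in window %d (movement %s, trial %d)",
                   bad, i, w$movement, w$trial_index), call. = FALSE)
    }
    mat[i, ] <- row
    meta$label[i] <- w$movement
    meta$trial[i] <- w$trial_index
    meta$window_index[i] <- w$window_index
    meta$subject[i] <- w$subject_id
  }
  fm <- cbind(as.data.frame(mat), meta)
  attr(fm, "feature_cols") <- cols
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature columns of a feature matrix
#' @param fm a `feature_matrix` from [extract_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(fm) {
  fc <- attr(fm, "feature_cols")
  if (is.null(fc)) setdiff(names(fm), c("label", "trial", "window_index", "subject"))
  else fc
}

#' End-to-end feature extraction from a dataset of trials
#'
#' Preprocesses each trial (band-pass + notch), segments it disjointly, and
#' extracts `spec` features from every window.
#'
#' @param dataset list of [trial_recording()].
#' @param spec a [feature_set()].
#' @param window_ms analysis window in milliseconds.
#' @param preprocess apply the digital front end first (default `TRUE`).
#' @param notch_hz notch frequency forwarded to [preprocess_trial()].
#' @return A `feature_matrix`.
#' @export
dataset_features <- function(dataset, spec = feature_set("PROPOSED"),
                             window_ms = 250, preprocess = TRUE,
                             notch_hz = 50) {
  windows <- list()
  for (rec in dataset) {
    r <- if (preprocess) preprocess_trial(rec, notch_hz = notch_hz) else rec
    windows <- c(windows, segment_disjoint(r, window_ms))
  }
  extract_features(windows, spec)
}
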