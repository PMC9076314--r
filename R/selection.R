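#' The canonical 32-feature candidate pool
#'
#' All registry features considered by the greedy wrapper: the 18 classical
#' scalar statistics (MAV, IEMG, RMS, VAR, SSI, WL, ZC, SSC, WAMP, MYOP, LOG,
#' DAMV, DASDV, SKW, KURT, MOB, COM, MFL), the two nonlinear-scaling features
#' (LMAV, NSV), the four individually selectable autoregressive coefficients
#' (AR1--AR4), the six time-dependent power-spectrum descriptors, and the two
#' extra temporal-spatial descriptors (COV, TKEO) -- 32 candidates in all.
#'
#' @return Character vector of 32 feature names.
#' @export
default_pool <- function() {
  c("MAV", "IEMG", "RMS", "VAR", "SSI", "WL", "ZC", "SSC", "WAMP", "MYOP",
    "LOG", "DAMV", "DASDV", "SKW", "KURT", "MOB", "COM", "MFL",
    "LMAV", "NSV", paste0("AR", 1:4),
    "TM0", "TM0M2", "TM0M4", "TSPARS", "TIRF", "TWLR",
    "COV", "TKEO")
}

#' Greedy forward feature selection with a minimum-gain stopping rule
#'
#' Step 1 picks the single feature with the highest score. Every later step
#' scores the current set joined with each remaining candidate and accepts
#' the best extension only if its gain over the current score is at least
#' `min_gain` (default 0.25 percentage points); otherwise selection stops.
#' Ties are broken by pool order.
#'
#' @param pool character vector of candidate feature names.
#' @param evaluator function taking a character vector (feature subset) and
#'   returning a scalar score (e.g., cross-validated macro F1 in percent);
#'   must be deterministic for reproducible traces.
#' @param min_gain minimum score improvement to accept a new feature.
#' @return Object of class `selection_trace`: `selected` (ordered names),
#'   `scores` (score after each accepted step), `gains` (per-step gain),
#'   `stop_reason` (`"min_gain"` or `"pool_exhausted"`).
#' @export
forward_select <- function(pool, evaluator, min_gain = 0.25) {
  if (length(pool) == 0) stop("candidate pool is empty", call. = FALSE)
  score_subset <- function(subset) {
    s <- tryCatch(evaluator(subset), error = function(e) {
      stop(sprintf("evaluator failed on subset {%s}: %s",
                   paste(subset, collapse = ", "), conditionMessage(e)),
           call. = FALSE)
    })
    if (!is.numeric(s) || length(s) != 1 || !is.finite(s)) {
      stop(sprintf("evaluator returned a non-scalar score on subset {%s}",
                   paste(subset, collapse = ", ")), call. = FALSE)
    }
    s
  }
  remaining <- pool
  selected <- character(0)
  scores <- numeric(0)
  gains <- numeric(0)
  current <- -Inf
  stop_reason <- "pool_exhausted"
  while (length(remaining) > 0) {
    cand_scores <- vapply(remaining, function(f) score_subset(c(selected, f)),
                          numeric(1))
    best_i <- which.max(cand_scores)   # which.max keeps the first tie => pool order
    best <- unname(cand_scores[best_i])
    gain <- if (is.finite(current)) best - current else best
    if (length(selected) > 0 && gain < min_gain) {
      stop_reason <- "min_gain"
      break
    }
    selected <- c(selected, remaining[best_i])
    remaining <- remaining[-best_i]
    scores <- c(scores, best)
    gains <- c(gains, gain)
    current <- best
  }
  structure(list(selected = selected, scores = scores, gains = gains,
                 stop_reason = stop_reason, min_gain = min_gain),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d features selected (stop: %s)\n",
              length(x$selected), x$stop_reason))
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %2d. %-6s score %8.4f (gain %+.4f)\n",
                i, x$selected[i], x$scores[i], x$gains[i]))
  }
  invisible(x)
}

#' Cross-validation evaluator factory for forward selection
#'
#' Builds an evaluator closure that extracts the given feature subset from a
#' dataset and returns the trial-wise cross-validated macro score (percent).
#' Feature extraction is done once for the full pool and subsets are selected
#' by column, so the greedy search stays fast and deterministic.
#'
#' @param dataset list of [trial_recording()].
#' @param model classifier passed to [trialwise_cv_features()].
#' @param metric `"f1"` (default) or `"accuracy"`.
#' @param window_ms analysis window.
#' @param params a [feature_params()] list.
#' @return Function mapping a feature-name vector to a scalar score.
#' @export
cv_evaluator <- function(dataset, model = "lda", metric = c("f1", "accuracy"),
                         window_ms = 250, params = feature_params()) {
  metric <- match.arg(metric)
  pool_spec <- feature_set("custom",
                           features = c("MAV", "IEMG", "RMS", "VAR", "SSI",
                                        "WL", "ZC", "SSC", "WAMP", "MYOP",
                                        "LOG", "DAMV", "DASDV", "SKW", "KURT",
                                        "MOB", "COM", "MFL", "LMAV", "NSV",
                                        paste0("AR", 1:4), "TDPSD", "COV",
                                        "TKEO"),
                           params = params)
  fm <- dataset_features(dataset, pool_spec, window_ms = window_ms)
  n_ch <- length(grep("^MAV_ch", feature_cols(fm)))
  function(subset) {
    cols <- as.vector(outer(subset, seq_len(n_ch),
                            function(f, k) paste0(f, "_ch", k)))
    missing <- setdiff(cols, names(fm))
    if (length(missing)) stop("unknown feature columns: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    sub <- fm[, c(cols, "label", "trial", "window_index", "subject")]
    attr(sub, "feature_cols") <- cols
    class(sub) <- c("feature_matrix", "data.frame")
    rep <- trialwise_cv_features(sub, model = model)
    if (metric == "f1") rep$macro["f1"] else rep$macro["accuracy"]
  }
}
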