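#' Train-and-predict with the three standard myocontrol classifiers
#'
#' \describe{
#'   \item{`lda`}{Gaussian discriminant with per-class covariance (quadratic
#'     boundary, [MASS::qda()]); set `lda_pooled = TRUE` for the
#'     pooled-covariance linear variant ([MASS::lda()]).}
#'   \item{`svm`}{RBF-kernel support vector machine, one-vs-one multiclass,
#'     kernel width sigma = 1 (i.e. `gamma = 0.5` under
#'     `exp(-gamma ||u - v||^2)`), via [e1071::svm()]. Inputs are not
#'     re-standardized: ULDA-reduced features are already whitened against
#'     total scatter.}
#'   \item{`knn`}{k-nearest neighbours with cityblock (L1) distance, k = 3,
#'     majority vote; vote ties are broken by the smallest summed distance.}
#' }
#'
#' @param train,test `feature_matrix` objects sharing feature columns; train
#'   must contain every class.
#' @param model `"lda"`, `"svm"`, or `"knn"`.
#' @param lda_pooled use pooled covariance for `model = "lda"`.
#' @param k,sigma classifier hyper-parameters.
#' @return Character vector of predicted labels, one per test row.
#' @export
classify <- function(train, test, model = c("lda", "svm", "knn"),
                     lda_pooled = FALSE, k = 3, sigma = 1) {
  model <- match.arg(model)
  fc <- feature_cols(train)
  if (!all(fc %in% names(test))) {
    stop("train and test feature columns differ", call. = FALSE)
  }
  Xtr <- as.matrix(train[, fc, drop = FALSE])
  Xte <- as.matrix(test[, fc, drop = FALSE])
  ytr <- factor(train$label)
  if (model == "lda") {
    fit <- if (lda_pooled) MASS::lda(Xtr, grouping = ytr)
           else MASS::qda(Xtr, grouping = ytr)
    as.character(stats::predict(fit, Xte)$class)
  } else if (model == "svm") {
    fit <- e1071::svm(Xtr, ytr, kernel = "radial", gamma = 1 / (2 * sigma^2),
                      scale = FALSE)
    as.character(stats::predict(fit, Xte))
  } else {
    knn_cityblock(Xtr, ytr, Xte, k = k)
  }
}

# L1-metric k-nearest-neighbour majority vote; ties broken by smallest summed
# distance among the tied classes.
knn_cityblock <- function(Xtr, ytr, Xte, k = 3) {
  ytr <- as.character(ytr)
  n_tr <- nrow(Xtr)
  if (k > n_tr) stop("k exceeds the number of training samples", call. = FALSE)
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- colSums(abs(t(Xtr) - Xte[i, ]))
    nn <- order(d)[seq_len(k)]
    votes <- table(ytr[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      dsum <- vapply(top, function(cl) sum(d[nn][ytr[nn] == cl]), numeric(1))
      top <- top[which.min(dsum)]
    }
    out[i] <- top
  }
  out
}

#' Per-movement and macro metrics from a confusion matrix
#'
#' One-vs-rest counts per movement m: `TP = C[m,m]`, `FN = rowsum - TP`,
#' `FP = colsum - TP`, `TN = total - TP - FN - FP`; then accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2 P S / (P + S)`, all in percent. Macro values are unweighted means over
#' movements. A zero-denominator metric is reported as 0 with a warning so
#' sweep aggregation stays total.
#'
#' @param confusion square non-negative integer matrix, rows = true class,
#'   columns = predicted class.
#' @return List with `per_movement` (data.frame) and `macro` (named numeric
#'   vector of the five metrics, percent).
#' @export
metrics_from_confusion <- function(confusion) {
  C <- as.matrix(confusion)
  if (nrow(C) != ncol(C) || any(C < 0)) {
    stop("confusion must be a square non-negative matrix", call. = FALSE)
  }
  K <- nrow(C)
  total <- sum(C)
  cls <- rownames(C)
  if (is.null(cls)) cls <- as.character(seq_len(K))
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %s (zero denominator); reported as 0",
                      what, cl), call. = FALSE)
      return(0)
    }
    num / den
  }
  pm <- data.frame(movement = cls, tp = NA_real_, tn = NA_real_, fp = NA_real_,
                   fn = NA_real_, accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, precision = NA_real_, f1 = NA_real_,
                   stringsAsFactors = FALSE)
  for (m in seq_len(K)) {
    tp <- C[m, m]
    fn <- sum(C[m, ]) - tp
    fp <- sum(C[, m]) - tp
    tn <- total - tp - fn - fp
    acc <- safe_div(tp + tn, total, "accuracy", cls[m])
    sens <- safe_div(tp, tp + fn, "sensitivity", cls[m])
    spec <- safe_div(tn, tn + fp, "specificity", cls[m])
    prec <- safe_div(tp, tp + fp, "precision", cls[m])
    f1 <- if (prec + sens == 0) {
      warning(sprintf("F1 undefined for class %s; reported as 0", cls[m]),
              call. = FALSE)
      0
    } else 2 * prec * sens / (prec + sens)
    pm[m, 2:10] <- c(tp, tn, fp, fn, 100 * acc, 100 * sens, 100 * spec,
                     100 * prec, 100 * f1)
  }
  macro <- c(accuracy = mean(pm$accuracy), sensitivity = mean(pm$sensitivity),
             specificity = mean(pm$specificity), precision = mean(pm$precision),
             f1 = mean(pm$f1))
  list(per_movement = pm, macro = macro)
}

confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Trial-wise (leave-one-trial-out) cross-validation on a feature matrix
#'
#' Fold t trains on all windows whose `trial != t` and tests on trial t, for
#' every trial index; ULDA is refitted inside each fold on training windows
#' only, so no test information leaks into the reduction. Per-fold confusion
#' matrices are aggregated into per-movement and macro metrics with
#' mean and SD across folds.
#'
#' @param fm a `feature_matrix` with `label` and `trial` columns; every
#'   movement must have the same set of trial indices.
#' @param model classifier for [classify()].
#' @param use_ulda reduce with per-fold ULDA before classifying (default
#'   `TRUE`).
#' @param ... forwarded to [classify()].
#' @return Object of class `eval_report`: `folds` (per-fold confusion and
#'   macro metrics), `confusion` (summed), `per_movement`, `macro`,
#'   `macro_sd`.
#' @export
trialwise_cv_features <- function(fm, model = "lda", use_ulda = TRUE, ...) {
  trials <- sort(unique(fm$trial))
  tab <- table(fm$label, fm$trial)
  if (any(tab == 0)) {
    stop("every movement needs windows in every trial for trial-wise CV",
         call. = FALSE)
  }
  classes <- sort(unique(as.character(fm$label)))
  folds <- list()
  fold_macros <- matrix(NA_real_, length(trials), 5,
                        dimnames = list(NULL, c("accuracy", "sensitivity",
                                                "specificity", "precision", "f1")))
  total_conf <- matrix(0, length(classes), length(classes),
                       dimnames = list(classes, classes))
  for (ti in seq_along(trials)) {
    t <- trials[ti]
    tr <- fm[fm$trial != t, , drop = FALSE]
    te <- fm[fm$trial == t, , drop = FALSE]
    attr(tr, "feature_cols") <- feature_cols(fm)
    attr(te, "feature_cols") <- feature_cols(fm)
    class(tr) <- class(te) <- c("feature_matrix", "data.frame")
    if (use_ulda) {
      proj <- ulda_fit(tr)
      tr <- ulda_transform(proj, tr)
      te <- ulda_transform(proj, te)
    }
    pred <- classify(tr, te, model = model, ...)
    conf <- confusion_matrix(te$label, pred, classes)
    m <- metrics_from_confusion(conf)
    folds[[ti]] <- list(trial = t, confusion = conf, macro = m$macro)
    fold_macros[ti, ] <- m$macro
    total_conf <- total_conf + as.matrix(conf)
  }
  agg <- metrics_from_confusion(total_conf)
  structure(list(folds = folds, confusion = total_conf,
                 per_movement = agg$per_movement,
                 macro = colMeans(fold_macros),
                 macro_sd = apply(fold_macros, 2, stats::sd),
                 model = model, n_folds = length(trials)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d folds\n", x$model, x$n_folds))
  for (m in names(x$macro)) {
    cat(sprintf("  macro %-11s %6.2f%% +/- %.2f\n", m, x$macro[m], x$macro_sd[m]))
  }
  invisible(x)
}

#' Full pipeline: preprocess, window, extract, reduce, cross-validate
#'
#' @param dataset list of [trial_recording()].
#' @param spec a [feature_set()].
#' @param model classifier for [classify()].
#' @param window_ms analysis window in milliseconds.
#' @param preprocess apply the digital front end (default `TRUE`).
#' @param ... forwarded to [classify()].
#' @return An `eval_report` (see [trialwise_cv_features()]).
#' @export
trialwise_cv <- function(dataset, spec = feature_set("PROPOSED"), model = "lda",
                         window_ms = 250, preprocess = TRUE, ...) {
  fm <- dataset_features(dataset, spec, window_ms = window_ms,
                         preprocess = preprocess)
  trialwise_cv_features(fm, model = model, ...)
}

#' Bonferroni-corrected one-way ANOVA between two score vectors
#'
#' Tests whether two paired per-subject score vectors (e.g., macro F1 of two
#' feature sets across 18 subjects) differ, with a one-way ANOVA whose p-value
#' is multiplied by the number of planned comparisons and capped at 1.
#'
#' @param scores_a,scores_b equal-length numeric vectors.
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @return Corrected p-value in `[0, 1]`.
#' @export
compare_bonferroni <- function(scores_a, scores_b, n_comparisons = 1) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2) {
    stop("score vectors must have equal length >= 2", call. = FALSE)
  }
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0) {
    return(if (mean(scores_a) == mean(scores_b)) 1 else 0)
  }
  d <- data.frame(score = c(scores_a, scores_b),
                  group = rep(c("A", "B"), each = length(scores_a)))
  p <- summary(stats::aov(score ~ group, data = d))[[1]][["Pr(>F)"]][1]
  min(1, p * n_comparisons)
}

#' Window-size robustness sweep
#'
#' Runs trial-wise CV at each window size in `grid_ms` (default 50--350 ms in
#' 50 ms steps) for the base feature set and for the base set augmented with
#' LMAV and NSV, recording mean and SD of every macro metric.
#'
#' @param dataset list of [trial_recording()].
#' @param base_features character vector of base feature names (default the
#'   11 classical members of the proposed set, i.e. it without LMAV/NSV).
#' @param model classifier.
#' @param grid_ms window sizes in milliseconds.
#' @param params a [feature_params()] list.
#' @return `sweep_result` data.frame: one row per (window size, variant) with
#'   macro metric means and SDs.
#' @export
sweep_window <- function(dataset,
                         base_features = c("WL", "WAMP", "SSC", "ZC", "MOB",
                                           "COM", "SKW", paste0("AR", 1:4)),
                         model = "lda", grid_ms = seq(50, 350, by = 50),
                         params = feature_params()) {
  variants <- list(base = base_features,
                   with_lmav_nsv = c("LMAV", "NSV", base_features))
  rows <- list()
  for (wms in grid_ms) {
    for (v in names(variants)) {
      spec <- feature_set("custom", features = variants[[v]], params = params)
      rep <- trialwise_cv(dataset, spec, model = model, window_ms = wms)
      rows[[length(rows) + 1]] <- data.frame(
        window_ms = wms, variant = v, t(rep$macro),
        f1_sd = rep$macro_sd["f1"], accuracy_sd = rep$macro_sd["accuracy"],
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' SNR robustness sweep
#'
#' For each SNR in `grid_db` (default 0--20 dB in 1 dB steps), contaminates
#' every raw trial with AWGN at that SNR (before digital preprocessing), then
#' runs trial-wise CV for the base feature set and for base + {LMAV, NSV}.
#' One seeded noise realization per trial per sweep point.
#'
#' @inheritParams sweep_window
#' @param grid_db SNR grid in dB.
#' @param window_ms analysis window.
#' @param seed master seed for the noise realizations.
#' @return `sweep_result` data.frame keyed by `snr_db` and `variant`.
#' @export
sweep_snr <- function(dataset,
                      base_features = c("WL", "WAMP", "SSC", "ZC", "MOB",
                                        "COM", "SKW", paste0("AR", 1:4)),
                      model = "lda", grid_db = 0:20, window_ms = 250,
                      seed = 1L, params = feature_params()) {
  variants <- list(base = base_features,
                   with_lmav_nsv = c("LMAV", "NSV", base_features))
  rows <- list()
  for (gi in seq_along(grid_db)) {
    snr <- grid_db[gi]
    noisy <- lapply(seq_along(dataset), function(i) {
      add_awgn(dataset[[i]], snr, seed = trial_seed(seed + 7919L * gi, i))
    })
    for (v in names(variants)) {
      spec <- feature_set("custom", features = variants[[v]], params = params)
      rep <- trialwise_cv(noisy, spec, model = model, window_ms = window_ms)
      rows[[length(rows) + 1]] <- data.frame(
        snr_db = snr, variant = v, t(rep$macro),
        f1_sd = rep$macro_sd["f1"], accuracy_sd = rep$macro_sd["accuracy"],
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
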