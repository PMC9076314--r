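sep_fm <- function(n = 60, gap = 6, seed = 41) {
  set.seed(seed)
  X <- rbind(cbind(stats::rnorm(n), stats::rnorm(n)),
             cbind(stats::rnorm(n) + gap, stats::rnorm(n)))
  colnames(X) <- c("F1", "F2")
  fm <- as.data.frame(X)
  fm$label <- rep(c("a", "b"), each = n)
  fm$trial <- rep(rep(1:3, length.out = n), 2)
  fm$window_index <- seq_len(2 * n) - 1L
  fm$subject <- "s"
  attr(fm, "feature_cols") <- c("F1", "F2")
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

test_that("all three classifiers solve far-separated Gaussian classes", {
  fm <- sep_fm()
  idx <- fm$trial != 3
  tr <- fm[idx, ]; te <- fm[!idx, ]
  attr(tr, "feature_cols") <- attr(te, "feature_cols") <- c("F1", "F2")
  class(tr) <- class(te) <- class(fm)
  for (m in c("lda", "svm", "knn")) {
    expect_identical(classify(tr, te, model = m), te$label)
  }
  expect_identical(classify(tr, te, model = "lda", lda_pooled = TRUE), te$label)
})

test_that("knn with three identical exemplars per class self-classifies perfectly", {
  X <- matrix(rep(c(0, 0, 5, 5), each = 3), ncol = 2)[, ]
  X <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  colnames(X) <- c("F1", "F2")
  fm <- as.data.frame(X)
  fm$label <- rep(c("a", "b"), each = 3)
  attr(fm, "feature_cols") <- c("F1", "F2")
  class(fm) <- c("feature_matrix", "data.frame")
  expect_identical(classify(fm, fm, model = "knn"), fm$label)
})

test_that("knn uses the cityblock metric, not Euclidean", {
  # test point at (0,0); class a trains at (3, 3.5) [L1 6.5, L2 4.61],
  # class b at (0, 5) [L1 5, L2 5]: L1 prefers b, L2 would prefer a.
  Xtr <- rbind(c(3, 3.5), c(3.1, 3.5), c(3, 3.6),
               c(0, 5), c(0.1, 5), c(0, 5.1))
  colnames(Xtr) <- c("F1", "F2")
  tr <- as.data.frame(Xtr)
  tr$label <- rep(c("a", "b"), each = 3)
  attr(tr, "feature_cols") <- c("F1", "F2")
  class(tr) <- c("feature_matrix", "data.frame")
  te <- tr[1, ]; te$F1 <- 0; te$F2 <- 0
  attr(te, "feature_cols") <- c("F1", "F2")
  class(te) <- class(tr)
  expect_identical(classify(tr, te, model = "knn", k = 3), "b")
})

test_that("confusion metrics match the hand-worked example and stay in bounds", {
  C <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("c1", "c2")))
  m <- metrics_from_confusion(C)
  r1 <- m$per_movement[1, ]
  expect_equal(r1$sensitivity, 80)
  expect_equal(r1$specificity, 90)
  expect_equal(r1$precision, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(r1$accuracy, 85)
  expect_equal(r1$f1, 100 * 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-9)

  d <- diag(c(5, 7, 9))
  md <- metrics_from_confusion(d)
  expect_true(all(md$macro == 100))

  u <- matrix(3, 10, 10)
  expect_equal(metrics_from_confusion(u)$macro[["sensitivity"]], 10)
})

test_that("metrics agree with direct label-pair counting on random confusions", {
  set.seed(42)
  for (i in 1:50) {
    K <- sample(2:8, 1)
    classes <- paste0("c", seq_len(K))
    truth <- sample(classes, 200, replace = TRUE)
    pred <- ifelse(stats::runif(200) < 0.7, truth, sample(classes, 200, TRUE))
    C <- table(factor(truth, levels = classes), factor(pred, levels = classes))
    m <- suppressWarnings(metrics_from_confusion(as.matrix(C)))
    o <- oracle_metrics(truth, pred, classes)
    for (col in colnames(o)) {
      expect_equal(m$per_movement[[col]], unname(o[, col]), tolerance = 1e-9)
    }
    expect_true(all(m$per_movement[, 6:10] >= 0 & m$per_movement[, 6:10] <= 100))
    # F1 is the harmonic mean of that movement's own precision and sensitivity
    ps <- m$per_movement$precision + m$per_movement$sensitivity
    f1 <- ifelse(ps > 0, 2 * m$per_movement$precision * m$per_movement$sensitivity / ps, 0)
    expect_equal(m$per_movement$f1, f1, tolerance = 1e-9)
  }
})

test_that("trial-wise CV keeps folds disjoint and fold sizes exact", {
  cfg <- small_config(seed = 43, n_trials = 3, duration_s = 1)
  fm <- dataset_features(generate_dataset(cfg), feature_set("FS2"))
  rep <- trialwise_cv_features(fm, model = "lda", lda_pooled = TRUE)
  expect_equal(rep$n_folds, 3)
  # each fold tests exactly windows-per-trial x movements windows
  wpt <- 4  # 1 s at 2000 Hz / 250 ms
  for (f in rep$folds) {
    expect_equal(sum(f$confusion), wpt * 10)
  }
  expect_equal(sum(rep$confusion), nrow(fm))
  expect_error(trialwise_cv_features(fm[fm$trial != 1 | fm$label != "T", ]),
               "every trial")
})

test_that("a noiseless amplitude-coded dataset is classified perfectly", {
  cfg <- synth_config(n_trials = 3, duration_s = 1, noise_rms = 0, seed = 44)
  rep <- trialwise_cv(generate_dataset(cfg), feature_set("PROPOSED"),
                      model = "lda", lda_pooled = TRUE)
  expect_equal(unname(rep$macro["f1"]), 100)
})

test_that("the full pipeline is deterministic given the seed", {
  cfg <- small_config(seed = 45, n_trials = 3, duration_s = 1)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  r1 <- trialwise_cv(ds1, feature_set("FS2"), model = "lda", lda_pooled = TRUE)
  r2 <- trialwise_cv(ds2, feature_set("FS2"), model = "lda", lda_pooled = TRUE)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$macro, r2$macro)
})

test_that("Bonferroni ANOVA matches the squared-t identity and handles edge cases", {
  expect_equal(compare_bonferroni(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_bonferroni(rep(1, 5), rep(2, 5)), 0)
  expect_equal(compare_bonferroni(rep(1, 5), rep(1, 5)), 1)
  set.seed(46)
  a <- stats::rnorm(12); b <- stats::rnorm(12, mean = 0.8)
  p_aov <- compare_bonferroni(a, b, n_comparisons = 1)
  p_t <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t, tolerance = 1e-9)   # two-group ANOVA F = t^2
  expect_equal(compare_bonferroni(a, b, n_comparisons = 4),
               min(1, 4 * p_t), tolerance = 1e-9)
  expect_error(compare_bonferroni(1, 2), "equal length")
})

test_that("well-separated groups are detected in nearly all seeded replicates", {
  set.seed(47)
  hits <- 0
  for (i in 1:100) {
    a <- stats::rnorm(18)
    b <- stats::rnorm(18, mean = 5)
    if (compare_bonferroni(a, b, n_comparisons = 10) < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("sweep grids carry both variants at every axis point", {
  cfg <- weak_movement_config(seed = 48, n_trials = 3, duration_s = 2)
  ds <- generate_dataset(cfg)
  sw <- sweep_window(ds, base_features = c("WL", "SSC", "ZC"), model = "lda",
                     grid_ms = c(150, 250))
  expect_equal(sort(unique(sw$window_ms)), c(150, 250))
  expect_equal(as.integer(table(sw$window_ms)), rep(2L, 2))
  expect_true(all(c("base", "with_lmav_nsv") %in% sw$variant))

  sn <- sweep_snr(ds, base_features = c("WL", "SSC", "ZC"), model = "lda",
                  grid_db = c(5, 15), window_ms = 250, seed = 48)
  expect_equal(sort(unique(sn$snr_db)), c(5, 15))
  expect_true(all(sn$f1 >= 0 & sn$f1 <= 100))
})

test_that("fold SD of the F1 score tends downward as windows lengthen", {
  cfg <- small_config(seed = 49, n_trials = 6, duration_s = 5)
  ds <- generate_dataset(cfg)
  fm50 <- trialwise_cv(ds, feature_set("FS2"), model = "lda", window_ms = 50)
  fm350 <- trialwise_cv(ds, feature_set("FS2"), model = "lda", window_ms = 350)
  expect_lte(fm350$macro_sd[["f1"]], fm50$macro_sd[["f1"]] + 1)
})
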