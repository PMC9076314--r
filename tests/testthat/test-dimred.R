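make_fm <- function(X, labels, trials = NULL) {
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  fm <- as.data.frame(X)
  fm$label <- labels
  fm$trial <- if (is.null(trials)) 1L else trials
  fm$window_index <- seq_len(nrow(X)) - 1L
  fm$subject <- "s"
  attr(fm, "feature_cols") <- colnames(X)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

test_that("ULDA reduces 10 classes to 9 uncorrelated dimensions", {
  cfg <- small_config(seed = 21)
  ds <- generate_dataset(cfg)
  fm <- dataset_features(ds, feature_set("PROPOSED"))
  proj <- ulda_fit(fm)
  expect_equal(proj$r, 9)
  X <- as.matrix(fm[, feature_cols(fm)])
  St <- crossprod(sweep(X, 2, colMeans(X)))
  G <- proj$projection
  expect_lt(max(abs(t(G) %*% St %*% G - diag(proj$r))), 1e-6)
})

test_that("ULDA separates constructed well-separated Gaussian classes", {
  set.seed(22)
  n <- 60
  X <- rbind(matrix(stats::rnorm(n * 5), n, 5),
             matrix(stats::rnorm(n * 5), n, 5))
  X[(n + 1):(2 * n), 1] <- X[(n + 1):(2 * n), 1] + 8
  fm <- make_fm(X, rep(c("a", "b"), each = n))
  proj <- ulda_fit(fm)
  expect_equal(proj$r, 1)
  z <- ulda_transform(proj, fm)$ULDA1
  mu <- tapply(z, fm$label, mean)
  pooled_sd <- sqrt(mean(tapply(z, fm$label, stats::var)))
  expect_gt(abs(mu[1] - mu[2]) / pooled_sd, 4)
})

test_that("ULDA projection ignores class label names and transform is linear", {
  set.seed(23)
  X <- matrix(stats::rnorm(300), 100, 3)
  X[1:50, ] <- X[1:50, ] + 2
  labs <- rep(c("a", "b"), each = 50)
  proj1 <- ulda_fit(make_fm(X, labs))
  proj2 <- ulda_fit(make_fm(X, rep(c("z", "y"), each = 50)))
  # same subspace up to column sign
  expect_equal(abs(proj1$projection), abs(proj2$projection), tolerance = 1e-8)

  fm <- make_fm(X, labs)
  Z <- ulda_transform(proj1, fm)
  # duplicate rows map to duplicate rows
  fm2 <- make_fm(X[c(1, 1, 2), ], c("a", "a", "b"))
  Z2 <- ulda_transform(proj1, fm2)
  expect_equal(Z2$ULDA1[1], Z2$ULDA1[2])
  # zero feature vector maps to -G' mu
  fm0 <- make_fm(matrix(0, 1, 3), "a")
  expect_equal(as.numeric(ulda_transform(proj1, fm0)$ULDA1),
               as.numeric(-t(proj1$projection) %*% proj1$center))
  expect_error(ulda_fit(make_fm(X, rep("a", 100))), "two classes")
  expect_error(ulda_transform(proj1, make_fm(matrix(0, 1, 2), "a")), "match")
})

test_that("min-max normalization maps each feature onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_error(minmax_normalize(c(1, 1, 1)), "constant")
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(minmax_normalize(m), "constant")
  dropped <- minmax_normalize(m, on_constant = "drop")
  expect_equal(colnames(dropped), "a")
})

test_that("RES index matches the hand-computed two-class value and its oracle", {
  pts <- rbind(c(0, 0), c(0, 2), c(3, 0), c(3, 2))
  labs <- c("A", "A", "B", "B")
  expect_equal(res_index(pts, labs), 3 / (sqrt(2) / 2), tolerance = 1e-12)
  set.seed(24)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    n <- 10
    pts <- matrix(stats::rnorm(2 * K * n), ncol = 2)
    pts[, 1] <- pts[, 1] + rep(seq_len(K) * 2, each = n)
    labs <- rep(letters[seq_len(K)], each = n)
    expect_equal(res_index(pts, labs), oracle_res(pts, labs), tolerance = 1e-9)
  }
})

test_that("RES is invariant to translation and scaling, and errors on bad input", {
  set.seed(25)
  pts <- matrix(stats::rnorm(80), ncol = 2)
  labs <- rep(c("a", "b", "c", "d"), each = 10)
  pts[, 1] <- pts[, 1] + rep(1:4, each = 10)
  r0 <- res_index(pts, labs)
  expect_equal(res_index(pts + 13.7, labs), r0, tolerance = 1e-9)
  expect_equal(res_index(pts * 0.003, labs), r0, tolerance = 1e-9)
  expect_error(res_index(matrix(0, 4, 3), c("a", "a", "b", "b")), "exactly 2")
  expect_error(res_index(pts, rep("a", 40)), "2 classes")
  same <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_error(res_index(same, c("a", "a", "b", "b")), "degenerate")
})

test_that("RES grows monotonically with synthetic class amplitude gaps", {
  res_at_gap <- function(gap) {
    movs <- c("A", "B")
    amps <- matrix(c(0.5, 0.5, 0.5 * (1 + gap), 0.5 * (1 + gap)), 2, 2,
                   byrow = TRUE, dimnames = list(movs, NULL))
    cfg <- synth_config(movements = movs, amplitudes = amps, n_trials = 3,
                        duration_s = 2, noise_rms = 0.1, seed = 26)
    fm <- dataset_features(generate_dataset(cfg), feature_set("FS2"))
    proj <- ulda_fit(fm)
    Z <- ulda_transform(proj, fm)
    # 2-class ULDA is 1-D; pad with the best original feature? Use first two
    # normalized FS2 features instead for a 2-D embedding.
    P <- cbind(Z$ULDA1, fm$WL_ch1)
    res_index(P, fm$label)
  }
  vals <- vapply(c(0.5, 1.5, 4), res_at_gap, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("scatter export honors the conventional point count and unit square", {
  cfg <- synth_config(seed = 27)   # full-size: 10 movements x 6 trials x 5 s
  ds <- generate_dataset(cfg)
  fm <- dataset_features(ds, feature_set("PROPOSED"))
  sc <- export_scatter(fm, paper_points = TRUE)
  expect_equal(nrow(sc), 300)      # 5 points x 6 trials x 10 movements
  expect_true(all(sc$f1 >= 0 & sc$f1 <= 1))
  expect_true(all(sc$f2 >= 0 & sc$f2 <= 1))
  expect_gt(attr(sc, "res"), 0)
  full <- export_scatter(fm, paper_points = FALSE)
  expect_equal(nrow(full), 1200)   # all 20 windows per trial
})

test_that("true labels separate better than shuffled labels on a separable fixture", {
  movs <- c("A", "B")
  amps <- matrix(c(0.3, 0.3, 1.5, 1.5), 2, 2, byrow = TRUE,
                 dimnames = list(movs, NULL))
  cfg <- synth_config(movements = movs, amplitudes = amps, n_trials = 3,
                      duration_s = 2, noise_rms = 0.05, seed = 28)
  fm <- dataset_features(generate_dataset(cfg), feature_set("FS2"))
  proj <- ulda_fit(fm)
  Z <- ulda_transform(proj, fm)
  P <- cbind(Z$ULDA1, fm$WL_ch1)
  set.seed(29)
  expect_gt(res_index(P, fm$label), res_index(P, sample(fm$label)))
})
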