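# Independent brute-force oracles: direct loops over the defining sums,
# written without reference to the package implementations they check.

oracle_lmav <- function(x) {
  s <- 0
  for (xi in x) s <- s + abs(xi)
  log(max(1e-12, s / length(x)))
}

oracle_nsv <- function(x) {
  xbar <- 0
  for (xi in x) xbar <- xbar + abs(xi)
  xbar <- xbar / length(x)
  acc <- 0
  for (xi in x) {
    d <- xbar - xi
    croot <- sign(d) * abs(d)^(1 / 3)   # real signed cube root
    acc <- acc + croot^2
  }
  log(max(1e-12, acc / length(x)))
}

oracle_snr_db <- function(raw_rms, noise_rms) {
  20 * log10(sqrt(raw_rms^2 - noise_rms^2) / noise_rms)
}

oracle_res <- function(points, labels) {
  classes <- sort(unique(labels))
  K <- length(classes)
  m <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    m[k, 1] <- mean(points[idx, 1])
    m[k, 2] <- mean(points[idx, 2])
  }
  ed <- 0
  for (p in 1:(K - 1)) for (q in (p + 1):K) {
    ed <- ed + sqrt((m[p, 1] - m[q, 1])^2 + (m[p, 2] - m[q, 2])^2)
  }
  ed <- 2 / (K * (K - 1)) * ed
  ssum <- 0
  for (i in 1:2) for (k in seq_len(K)) {
    ssum <- ssum + sd(points[labels == classes[k], i])
  }
  ed / (ssum / (2 * K))
}

# Metrics recomputed by counting label pairs directly (never via the
# confusion-algebra shortcut used by the implementation).
oracle_metrics <- function(truth, pred, classes) {
  out <- matrix(NA_real_, length(classes), 5,
                dimnames = list(classes, c("accuracy", "sensitivity",
                                           "specificity", "precision", "f1")))
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    acc <- (tp + tn) / (tp + tn + fp + fn)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    out[cl, ] <- 100 * c(acc, sens, spec, prec, f1)
  }
  out
}

# Brute-force classical features.
oracle_mav <- function(x) { s <- 0; for (xi in x) s <- s + abs(xi); s / length(x) }
oracle_wl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}
oracle_zc <- function(x, thr = 0) {
  n <- 0
  for (i in 1:(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i + 1] - x[i]) >= thr) n <- n + 1
  }
  n
}
oracle_ssc <- function(x, thr = 0) {
  n <- 0
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= thr) n <- n + 1
  }
  n
}
oracle_wamp <- function(x, thr) {
  n <- 0
  for (i in 1:(length(x) - 1)) if (abs(x[i + 1] - x[i]) >= thr) n <- n + 1
  n
}
oracle_var <- function(x) {
  mu <- mean(x); s <- 0
  for (xi in x) s <- s + (xi - mu)^2
  s / (length(x) - 1)
}
oracle_mob <- function(x) sqrt(oracle_var(diff(x)) / oracle_var(x))
oracle_com <- function(x) oracle_mob(diff(x)) / oracle_mob(x)
oracle_skw <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3)
  m3 / m2^1.5
}
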