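#' Fit an uncorrelated linear discriminant analysis (ULDA) projection
#'
#' Finds a projection `G` maximizing between-class scatter subject to the
#' uncorrelatedness constraint `G' S_t G = I`, where `S_t` is the training
#' total-scatter matrix `sum_i (x_i - mu)(x_i - mu)'`. Computed by whitening
#' with the SVD of the centred data and then taking the leading left singular
#' vectors of the whitened between-class scatter, which is robust to singular
#' within-class scatter. The output dimensionality is at most
#' `n_classes - 1`.
#'
#' @param fm a `feature_matrix` (or plain data.frame with a `label` column).
#' @param tol relative singular-value cutoff for rank truncation.
#' @return Object of class `ulda_projection` with `projection`
#'   (`[n_features x r]`), `center` (training mean), `classes`, `r`,
#'   `feature_cols`.
#' @export
ulda_fit <- function(fm, tol = 1e-10) {
  fc <- feature_cols(fm)
  X <- as.matrix(fm[, fc, drop = FALSE])
  y <- as.character(fm$label)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("ULDA needs at least two classes", call. = FALSE)
  if (any(table(y) < 2)) stop("ULDA needs at least two samples per class",
                              call. = FALSE)
  mu <- colMeans(X)
  Hc <- sweep(X, 2, mu)                      # S_t = Hc' Hc
  sv <- svd(Hc)
  keep <- sv$d > tol * max(sv$d)
  U1 <- sv$v[, keep, drop = FALSE]
  Dinv <- 1 / sv$d[keep]
  # class means, weighted so Hb' Hb is the between-class scatter
  M <- t(vapply(classes, function(k) {
    nk <- sum(y == k)
    sqrt(nk) * (colMeans(X[y == k, , drop = FALSE]) - mu)
  }, numeric(ncol(X))))
  W <- U1 %*% diag(Dinv, nrow = length(Dinv))         # whitening: W' S_t W = I
  B <- t(W) %*% t(M)                                  # whitened class means (t x K)
  svb <- svd(B)
  q <- min(sum(svb$d > tol * max(svb$d, .Machine$double.eps)), K - 1)
  P <- svb$u[, seq_len(q), drop = FALSE]
  G <- W %*% P
  dimnames(G) <- list(fc, paste0("ULDA", seq_len(q)))
  structure(list(projection = G, center = mu, classes = classes, r = q,
                 feature_cols = fc),
            class = "ulda_projection")
}

#' @export
print.ulda_projection <- function(x, ...) {
  cat(sprintf("<ulda_projection> %d features -> %d dims, %d classes\n",
              nrow(x$projection), x$r, length(x$classes)))
  invisible(x)
}

#' Apply a fitted ULDA projection
#'
#' Centres by the training mean and projects: `Z = (X - mu) G`. Test data must
#' always be transformed with a projection fitted on training data only.
#'
#' @param proj a [ulda_fit()] result.
#' @param fm a `feature_matrix` with the same feature columns.
#' @return A `feature_matrix` whose feature columns are `ULDA1..ULDAr`;
#'   metadata columns are carried through.
#' @export
ulda_transform <- function(proj, fm) {
  stopifnot(inherits(proj, "ulda_projection"))
  if (!all(proj$feature_cols %in% names(fm))) {
    stop("feature columns of the data do not match the fitted projection",
         call. = FALSE)
  }
  X <- as.matrix(fm[, proj$feature_cols, drop = FALSE])
  Z <- sweep(X, 2, proj$center) %*% proj$projection
  meta_cols <- intersect(c("label", "trial", "window_index", "subject"), names(fm))
  out <- cbind(as.data.frame(Z), fm[, meta_cols, drop = FALSE])
  attr(out, "feature_cols") <- colnames(Z)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Min-max normalization to the unit interval
#'
#' Maps each column affinely so its minimum is 0 and maximum 1:
#' `(x - min) / (max - min)`.
#'
#' @param x numeric vector or matrix/data.frame of feature columns.
#' @param on_constant `"error"` (default) or `"drop"` for zero-range columns.
#' @return Same shape as `x`, each column in `[0, 1]`.
#' @export
minmax_normalize <- function(x, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  if (is.null(dim(x))) {
    r <- range(x)
    if (r[1] == r[2]) stop("constant feature cannot be min-max normalized",
                           call. = FALSE)
    return((x - r[1]) / (r[2] - r[1]))
  }
  m <- as.matrix(x)
  rng <- apply(m, 2, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const)) {
    if (on_constant == "error") {
      stop("constant feature(s) cannot be min-max normalized: ",
           paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    }
    m <- m[, !const, drop = FALSE]
    rng <- rng[, !const, drop = FALSE]
  }
  sweep(sweep(m, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' RES cluster separability index on a 2-D embedding
#'
#' Ratio of the mean pairwise Euclidean distance between class means to the
#' mean within-class standard deviation:
#' `ED = 2/(K(K-1)) sum_{p<q} sqrt((m1p-m1q)^2 + (m2p-m2q)^2)` over the K
#' class means, and `sigma = 1/(2K) sum over both coordinates and classes of
#' the per-class sample SD` (N-1 denominator). Higher values mean better
#' separated, tighter clusters; the index is invariant to rigid translation
#' and global scaling and is classifier-independent.
#'
#' @param points two-column numeric matrix/data.frame of embedded points.
#' @param labels class label per row (at least 2 classes, 2 points each).
#' @return Scalar RES index.
#' @export
res_index <- function(points, labels) {
  P <- as.matrix(points)
  if (ncol(P) != 2) {
    stop("RES index is defined on exactly 2 feature columns", call. = FALSE)
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2) stop("RES index needs at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("RES index needs at least 2 points per class", call. = FALSE)
  }
  means <- t(vapply(classes, function(k) colMeans(P[labels == k, , drop = FALSE]),
                    numeric(2)))
  ed <- 0
  for (p in 1:(K - 1)) {
    for (q in (p + 1):K) {
      ed <- ed + sqrt(sum((means[p, ] - means[q, ])^2))
    }
  }
  ed <- 2 / (K * (K - 1)) * ed
  sds <- vapply(classes, function(k) {
    apply(P[labels == k, , drop = FALSE], 2, stats::sd)
  }, numeric(2))
  sigma <- mean(sds)
  if (sigma <= 0) stop("degenerate clusters: zero mean within-class SD",
                       call. = FALSE)
  ed / sigma
}

#' Export a normalized 2-D ULDA scatter with its RES index
#'
#' Fits ULDA on the full feature matrix, keeps the first two discriminant
#' coordinates, min-max normalizes them to the unit square, and computes the
#' RES index of the embedding. In `paper_points = TRUE` mode every 4th window
#' is kept (5 points per 5 s trial at 250 ms windows), reproducing the
#' conventional 300-point scatter for 10 movements x 6 trials; otherwise all
#' windows are exported.
#'
#' @param fm a `feature_matrix` from [dataset_features()].
#' @param paper_points keep every 4th window per trial (default `FALSE`).
#' @return Object of class `scatter_data`: data.frame with `f1`, `f2`,
#'   `label` plus attribute `res` (the RES index).
#' @export
export_scatter <- function(fm, paper_points = FALSE) {
  proj <- ulda_fit(fm)
  if (proj$r < 2) stop("scatter export needs at least 2 ULDA dimensions",
                       call. = FALSE)
  Z <- ulda_transform(proj, fm)
  if (paper_points) {
    Z <- Z[Z$window_index %% 4L == 0L, , drop = FALSE]
  }
  nm <- minmax_normalize(Z[, c("ULDA1", "ULDA2")])
  out <- data.frame(f1 = nm[, 1], f2 = nm[, 2], label = Z$label,
                    stringsAsFactors = FALSE)
  attr(out, "res") <- res_index(out[, c("f1", "f2")], out$label)
  class(out) <- c("scatter_data", "data.frame")
  out
}

#' @export
print.scatter_data <- function(x, ...) {
  cat(sprintf("<scatter_data> %d points, %d classes, RES = %.4f\n",
              nrow(x), length(unique(x$label)), attr(x, "res")))
  invisible(x)
}
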