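#' Orientation class bins
#'
#' Equally spaced, right-open orientation classes covering [0, 180).
#' With the default 10 classes the bins are [0,18), [18,36), ..., [162,180)
#' with centers 9, 27, ..., 171 degrees.
#'
#' @param n_classes Number of classes (>= 2).
#' @return A list of class `class_bins` with `n_classes`, `edges`,
#'   `centers`, `width`.
#' @export
class_bins <- function(n_classes = 10) {
  if (n_classes < 2) abort("`n_classes` must be >= 2.")
  width <- 180 / n_classes
  structure(
    list(n_classes = as.integer(n_classes),
         edges = width * (seq_len(n_classes) - 1),
         centers = width * (seq_len(n_classes) - 1) + width / 2,
         width = width),
    class = "class_bins"
  )
}

#' @rdname class_bins
#' @param ori Orientations in degrees.
#' @param bins A `class_bins` object.
#' @return `ori_class()` returns the 1-based class index of each
#'   orientation.
#' @export
ori_class <- function(ori, bins = class_bins()) {
  as.integer(floor(wrap_ori(ori) / bins$width)) + 1L
}

# seeded stratified fold assignment: within each class, shuffle then deal
# trials round-robin across folds
stratified_folds <- function(labels, n_folds, seed) {
  counts <- table(labels)
  if (any(counts < n_folds)) {
    bad <- counts[counts < n_folds]
    abort(paste0(
      "every class needs >= n_folds members for stratified CV; short classes: ",
      paste(sprintf("%s (n=%d)", names(bad), as.integer(bad)), collapse = ", ")))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# PCA on the training rows only, keeping the smallest number of components
# reaching `var_kept` of the training variance
fit_pca <- function(x, var_kept) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- svd(xc, nu = 0)
  pos <- s$d > max(s$d) * 1e-12
  ev <- s$d[pos]^2
  k <- which(cumsum(ev) / sum(ev) >= var_kept - 1e-12)[1]
  list(mu = mu, rot = s$v[, seq_len(k), drop = FALSE], k = k)
}

# LDA with analytic shrinkage of the pooled within-class covariance toward
# its diagonal. Returns the discriminant projection (q = n_classes - 1
# dimensions, capped by rank) and the projected class means.
fit_lda <- function(x, y, n_classes) {
  n <- nrow(x); p <- ncol(x)
  cls <- sort(unique(y))
  m_all <- colMeans(x)
  xc <- x
  means <- matrix(0, length(cls), p)
  for (i in seq_along(cls)) {
    r <- y == cls[i]
    means[i, ] <- colMeans(x[r, , drop = FALSE])
    xc[r, ] <- sweep(x[r, , drop = FALSE], 2, means[i, ])
  }
  s_w <- crossprod(xc) / n
  # analytic shrinkage level toward diag(s_w): variance of the sample
  # covariances over squared off-diagonal mass (Ledoit-Wolf style)
  ssq <- rowSums(xc^2)
  b2 <- (sum(ssq^2) - n * sum(s_w^2)) / n^2
  d2 <- sum(s_w^2) - sum(diag(s_w)^2)
  lambda <- if (d2 <= 0) 1 else min(1, max(0, b2 / d2))
  sigma <- (1 - lambda) * s_w + lambda * diag(diag(s_w), p)
  diag(sigma) <- diag(sigma) + max(diag(sigma)) * 1e-10

  r_chol <- chol(sigma)
  wh <- backsolve(r_chol, diag(p))     # whitening: x %*% wh
  mw <- means %*% wh
  mw_c <- sweep(mw, 2, colMeans(mw))
  n_g <- as.vector(table(factor(y, levels = cls)))
  s_b <- crossprod(mw_c * sqrt(n_g / n))
  e <- eigen(s_b, symmetric = TRUE)
  q <- min(n_classes - 1, sum(e$values > max(e$values, 0) * 1e-10), p)
  q <- max(q, 1)
  proj <- wh %*% e$vectors[, seq_len(q), drop = FALSE]
  list(proj = proj, class_means = means %*% proj, classes = cls,
       lambda = lambda, q = q)
}

#' Cross-validated spatiotemporal LDA decoding
#'
#' For every time point, independently: reduce the training fold with PCA
#' keeping `var_kept` of the variance (fit on training data only), fit a
#' shrinkage-regularized LDA projecting into the (`n_classes` - 1)-
#' dimensional discriminant space, project the held-out fold, and compute
#' each test trial's Euclidean distance to every training class mean.
#' Evidence for class k is the negated, class-mean-centered distance,
#' `-(d_k - mean_j d_j)`, so larger values mean the trial looks more like
#' that class and evidence sums to zero across classes.
#'
#' @param features An `ori_features` object from [build_features()].
#' @param labels Orientation in degrees per trial (length = n trials).
#' @param bins A [class_bins()] object.
#' @param n_folds Number of stratified cross-validation folds.
#' @param var_kept Fraction of training variance retained by PCA.
#' @param seed Seed for the fold assignment.
#' @param evidence `"distance"` (default, centered negated distance) or
#'   `"softmax"` (centered softmax likelihood of `-d^2/2`).
#' @return An object of class `ori_evidence`: `evidence`
#'   (trials x n_classes x time), `bins`, `times`, `labels`,
#'   `class_of_trial`, `fold_of_trial`, `trial_ids`.
#' @export
decode_cv <- function(features, labels, bins = class_bins(),
                      n_folds = 10, var_kept = 0.90, seed = 1,
                      evidence = c("distance", "softmax")) {
  stopifnot(inherits(features, "ori_features"), inherits(bins, "class_bins"))
  evidence <- match.arg(evidence)
  f <- features$features
  d <- dim(f)
  if (length(labels) != d[1]) abort("`labels` length must match the number of trials.")
  if (!all(is.finite(f))) abort("non-finite feature values.")
  if (anyNA(labels)) abort("`labels` must be defined for every trial.")
  y <- ori_class(labels, bins)
  fold <- stratified_folds(y, n_folds, seed)

  ev <- array(NA_real_, dim = c(d[1], bins$n_classes, d[3]))
  for (t in seq_len(d[3])) {
    x_t <- f[, , t]
    for (fd in seq_len(n_folds)) {
      tr <- fold != fd
      te <- fold == fd
      pca <- fit_pca(x_t[tr, , drop = FALSE], var_kept)
      z_tr <- sweep(x_t[tr, , drop = FALSE], 2, pca$mu) %*% pca$rot
      z_te <- sweep(x_t[te, , drop = FALSE], 2, pca$mu) %*% pca$rot
      lda <- fit_lda(z_tr, y[tr], bins$n_classes)
      dst <- class_distances(z_te %*% lda$proj, lda$class_means)
      # classes absent from training (cannot happen with valid stratification)
      ev[te, lda$classes, t] <- evidence_from_distances(dst, evidence)
    }
  }
  structure(
    list(evidence = ev, bins = bins, times = features$times,
         labels = labels, class_of_trial = y, fold_of_trial = fold,
         trial_ids = features$trial_ids, evidence_type = evidence),
    class = "ori_evidence"
  )
}

# Euclidean distances from each row of z to each class mean
class_distances <- function(z, means) {
  zz <- rowSums(z^2)
  mm <- rowSums(means^2)
  d2 <- outer(zz, mm, `+`) - 2 * z %*% t(means)
  sqrt(pmax(d2, 0))
}

evidence_from_distances <- function(dst, type) {
  if (type == "distance") {
    -(dst - rowMeans(dst))
  } else {
    w <- exp(-0.5 * sweep(dst^2, 1, apply(dst^2, 1, min)))
    p <- w / rowSums(w)
    p - rowMeans(p)
  }
}

#' @export
print.ori_evidence <- function(x, ...) {
  d <- dim(x$evidence)
  cat(sprintf("<ori_evidence> %d trials x %d classes x %d time points (%s)\n",
              d[1], d[2], d[3], x$evidence_type))
  invisible(x)
}

#' Tidy a class-evidence tensor
#'
#' @param x An `ori_evidence` object.
#' @param ... Unused.
#' @return Tibble with `trial`, `class`, `class_center`, `time`,
#'   `evidence`.
#' @export
tidy.ori_evidence <- function(x, ...) {
  d <- dim(x$evidence)
  tibble(
    trial = rep(x$trial_ids, times = d[2] * d[3]),
    class = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    class_center = rep(rep(x$bins$centers, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    evidence = as.vector(x$evidence)
  )
}
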