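#' One-dimensional cluster-based permutation test
#'
#' One-sample test of a subjects x points series against zero with
#' familywise control over contiguous clusters. Pointwise t statistics are
#' thresholded at the t quantile for `alpha_threshold`; maximal contiguous
#' supra-threshold runs form candidate clusters whose mass is the summed t.
#' The null distribution of the maximum cluster mass is built by randomly
#' flipping each subject's sign (whole series at once) `n_iter` times; each
#' observed cluster's p-value is the fraction of null maxima at least as
#' large as its |mass|, with the `(b + 1) / (m + 1)` correction. Points
#' with zero variance across subjects are excluded with a warning.
#'
#' @param series Numeric matrix, subjects x points (>= 5 subjects, >= 2
#'   points).
#' @param n_iter Number of sign-flip permutations.
#' @param alpha_threshold Pointwise cluster-forming alpha.
#' @param seed Integer seed.
#' @param tail `"two"` (clusters of either sign) or `"one"`
#'   (positive-going clusters only, threshold at one-sided alpha).
#' @return An object of class `cluster_result`: `clusters` (tibble with
#'   `start`, `end`, `mass`, `p`), `t_values`, `threshold_stat`,
#'   `null_max`, `n_iter`, `seed`, `excluded_points`.
#' @export
cluster_permutation_1d <- function(series, n_iter = 10000,
                                   alpha_threshold = 0.05, seed = 1,
                                   tail = c("two", "one")) {
  tail <- match.arg(tail)
  series <- as.matrix(series)
  n <- nrow(series); np <- ncol(series)
  if (n < 5) abort("at least 5 subjects are required.")
  if (np < 2) abort("at least 2 points are required.")
  if (!all(is.finite(series))) abort("`series` contains non-finite values.")

  ssq <- colSums(series^2)
  excluded <- which(apply(series, 2, sd) == 0)
  if (length(excluded) > 0) {
    warn(sprintf("%d constant point(s) excluded from cluster formation.",
                 length(excluded)))
  }
  thr <- if (tail == "two") qt(1 - alpha_threshold / 2, n - 1) else
    qt(1 - alpha_threshold, n - 1)

  t_of <- function(m) {
    # sd of sign-flipped data from fixed column sums of squares
    v <- (ssq - n * m^2) / (n - 1)
    t <- m * sqrt(n) / sqrt(v)
    t[v <= 0] <- 0
    if (length(excluded)) t[excluded] <- 0
    t
  }
  t_obs <- t_of(colMeans(series))
  clusters <- find_clusters(t_obs, thr, tail)

  null_max <- numeric(n_iter)
  withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
    m_perm <- (signs %*% series) / n
    for (b in seq_len(n_iter)) {
      tb <- t_of(m_perm[b, ])
      cl <- find_clusters(tb, thr, tail)
      null_max[b] <- if (nrow(cl) == 0) 0 else max(abs(cl$mass))
    }
  })
  if (nrow(clusters) > 0) {
    clusters$p <- vapply(clusters$mass, function(m) {
      (sum(null_max >= abs(m)) + 1) / (n_iter + 1)
    }, numeric(1))
  } else {
    clusters$p <- numeric(0)
  }
  structure(
    list(clusters = clusters, t_values = t_obs, threshold_stat = thr,
         null_max = null_max, n_iter = n_iter, seed = seed,
         alpha_threshold = alpha_threshold, tail = tail,
         excluded_points = excluded),
    class = "cluster_result"
  )
}

# maximal contiguous runs above +thr (and below -thr for two-tailed);
# mass = summed t within the run
find_clusters <- function(t, thr, tail = "two") {
  out <- run_bounds(t > thr)
  if (tail == "two") out <- rbind(out, run_bounds(t < -thr))
  if (nrow(out) == 0) {
    return(tibble(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  mass <- vapply(seq_len(nrow(out)),
                 function(i) sum(t[out[i, 1]:out[i, 2]]), numeric(1))
  res <- tibble(start = out[, 1], end = out[, 2], mass = mass)
  res[order(res$start), , drop = FALSE]
}

run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold |t| > %.3f, %d permutations\n",
              nrow(x$clusters), x$threshold_stat, x$n_iter))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' @rdname cluster_permutation_1d
#' @param x A `cluster_result` object.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname cluster_permutation_1d
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
         threshold_stat = x$threshold_stat,
         n_iter = x$n_iter)
}
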