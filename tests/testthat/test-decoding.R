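test_that("sliding-window features have the conventional dimensions", {
  # 306 channels x 30-sample window -> 9180-dimensional feature vector
  ep <- as_ori_epochs(array(rnorm(4 * 306 * 40), c(4, 306, 40)),
                      times = seq(0, by = 1 / 200, length.out = 40),
                      sfreq = 200)
  f <- build_features(ep, window_len = 30)
  expect_equal(dim(f$features)[2], 9180)
  expect_equal(dim(f$features)[3], 40 - 30 + 1)
  expect_equal(f$times[1], ep$times[30])
})

test_that("window 1 features equal scaled instantaneous channel values", {
  d <- array(rnorm(3 * 8 * 10), c(3, 8, 10))
  ep <- as_ori_epochs(d, seq(0, by = 0.01, length.out = 10), 100,
                      channel_types = c(rep("magnetometer", 4),
                                        rep("gradiometer", 4)))
  f <- build_features(ep, window_len = 1)
  expect_equal(f$features[, 1:4, 5], d[, 1:4, 5] * 20)
  expect_equal(f$features[, 5:8, 5], d[, 5:8, 5])
})

test_that("constant-in-time data gives identical features at every window", {
  d <- array(rep(rnorm(3 * 8), 10), c(3, 8, 10))
  ep <- as_ori_epochs(d, seq(0, by = 0.01, length.out = 10), 100)
  f <- build_features(ep, window_len = 4)
  for (j in 2:dim(f$features)[3]) {
    expect_equal(f$features[, , j], f$features[, , 1])
  }
  expect_error(build_features(ep, window_len = 11), "exceeds")
})

test_that("LDA distances match a closed-form oracle on a diagonal-scatter instance", {
  # within-class scatter is diagonal by construction, so shrinkage toward
  # the diagonal is a no-op and the discriminant axis is the x-axis; the
  # whitened distance to each class mean has a closed form
  x <- rbind(c(1, 2), c(-1, -2), c(1, -2), c(-1, 2),
             c(6, 2), c(4, -2), c(6, -2), c(4, 2))
  y <- c(1, 1, 1, 1, 2, 2, 2, 2)           # class means (0,0) and (5,0)
  fit <- serialbias:::fit_lda(x, y, n_classes = 2)
  expect_equal(fit$q, 1)
  s_w <- diag(c(1, 4))                      # pooled within covariance (/n)
  test_pt <- matrix(c(2, 1), 1)
  z <- test_pt %*% fit$proj
  d_pkg <- serialbias:::class_distances(z, fit$class_means)
  # oracle: the discriminant axis is x; distances scale by 1/sqrt(s_w[1,1])
  d_oracle <- abs(c(2 - 0, 2 - 5)) / sqrt(s_w[1, 1])
  expect_equal(sort(as.vector(d_pkg)), sort(d_oracle), tolerance = 1e-8)
})

test_that("the discriminant space has n_classes - 1 dimensions", {
  set.seed(10)
  n <- 200; p <- 20
  y <- rep(1:10, each = 20)
  centers <- matrix(rnorm(10 * p, sd = 4), 10, p)
  x <- centers[y, ] + matrix(rnorm(n * p), n, p)
  fit <- serialbias:::fit_lda(x, y, n_classes = 10)
  expect_equal(fit$q, 9)
  expect_equal(ncol(fit$proj), 9)
})

test_that("training-fold class means ignore test-fold data", {
  set.seed(11)
  x <- matrix(rnorm(60 * 6), 60, 6)
  y <- rep(1:3, each = 20)
  tr <- rep(c(TRUE, FALSE), 30)
  f1 <- serialbias:::fit_lda(x[tr, ], y[tr], 3)
  x2 <- x
  x2[!tr, ] <- 999          # corrupt held-out rows
  f2 <- serialbias:::fit_lda(x2[tr, ], y[tr], 3)
  expect_identical(f1, f2)
})

test_that("cross-validated decoding recovers far-separated classes", {
  # two orthogonal orientation patterns (45 vs 135 deg), strong signal
  tr <- simulate_trials(100, 100, c(1, 0, 0, 0), seed = 21)
  tr$ori2 <- rep(c(45, 135), 50)
  ep <- simulate_epochs(tr, test_neural_params(snr = 5), "grating2")
  f <- build_features(ep, window_len = 4)
  ev <- decode_cv(f, tr$ori2, class_bins(2), n_folds = 5, seed = 21)
  t_pk <- which.min(abs(ev$times - 0.3))
  hit <- mean(apply(ev$evidence[, , t_pk], 1, which.max) == ev$class_of_trial)
  expect_gt(hit, 0.95)
})

test_that("10-class evidence is centered and beats chance in the signal window", {
  sim <- sim_within_experiment(n_trials = 200, seed = 21, snr = 4, n_folds = 5)
  ev <- sim$evidence
  # class-axis centering invariant
  sums <- apply(ev$evidence, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  t_pk <- which.min(abs(ev$times - 0.3))
  hit <- mean(apply(ev$evidence[, , t_pk], 1, which.max) == ev$class_of_trial)
  expect_gt(hit, 0.4)   # chance is 0.1; adjacent-bin confusions expected
})

test_that("decoding rejects infeasible stratification with class counts", {
  ep <- as_ori_epochs(array(rnorm(30 * 8 * 6), c(30, 8, 6)),
                      seq(0, by = 0.02, length.out = 6), 50)
  f <- build_features(ep, window_len = 2)
  labels <- runif(30) * 180
  expect_error(decode_cv(f, labels, class_bins(10), n_folds = 10), "short classes")
})

test_that("alignment is a per-trial permutation peaking at offset zero", {
  sim <- sim_within_experiment(n_trials = 150, seed = 22, snr = 4, n_folds = 5)
  rel <- align_evidence(sim$evidence, sim$presented)
  expect_equal(rel$offsets, c(-72, -54, -36, -18, 0, 18, 36, 54, 72, 90))
  # permutation property: per-trial multiset of values is preserved
  t_pk <- which.min(abs(rel$times - 0.3))
  for (i in c(1, 50, 150)) {
    expect_equal(sort(rel$evidence[i, , t_pk]),
                 sort(sim$evidence$evidence[i, , t_pk]))
  }
  # tuned evidence peaks at zero offset on average
  curve <- apply(rel$evidence[, , t_pk], 2, mean)
  expect_equal(rel$offsets[which.max(curve)], 0)
})

test_that("cosine evidence follows its closed form and linearity", {
  offs <- c(-72, -54, -36, -18, 0, 18, 36, 54, 72, 90)
  mk_rel <- function(vals) {
    structure(list(evidence = array(rep(vals, each = 2), c(2, 10, 3)),
                   offsets = offs, times = c(0.1, 0.2, 0.3),
                   trial_ids = 1:2, dropped_trials = integer(0)),
              class = "ori_relevidence")
  }
  flat <- cosine_evidence(mk_rel(rep(1, 10)))
  expect_equal(as.vector(unclass(flat)), rep(0, 6), tolerance = 1e-12)
  # ev(k) = cos(2 offset_k) -> score = mean cos^2 = 0.5 over these 10 offsets
  tuned <- cosine_evidence(mk_rel(cos(2 * offs * pi / 180)))
  expect_equal(as.vector(unclass(tuned)), rep(0.5, 6), tolerance = 1e-12)
  flipped <- cosine_evidence(mk_rel(-cos(2 * offs * pi / 180)))
  expect_equal(unclass(flipped), -unclass(tuned))
})

test_that("label-permuted decoding shows no orientation evidence", {
  sim <- sim_within_experiment(n_trials = 150, seed = 23, snr = 2, n_folds = 5)
  feats_labels <- withr::with_seed(99, sample(sim$presented))
  # evidence decoded against permuted labels, aligned to those labels
  np <- test_neural_params(seed = 23 + 10000L)
  ep <- simulate_epochs(sim$trials, np, "grating2")
  f <- build_features(ep, window_len = 4)
  ev_perm <- decode_cv(f, feats_labels, class_bins(10), n_folds = 5, seed = 23)
  cs <- cosine_evidence(align_evidence(ev_perm, feats_labels))
  obs <- window_mean(cs, c(0.25, 0.6))
  # alignment-permutation null for the same tensor
  null <- withr::with_seed(7, replicate(200, {
    cs0 <- cosine_evidence(align_evidence(ev_perm, sample(feats_labels)))
    window_mean(cs0, c(0.25, 0.6))
  }))
  expect_lt(abs(obs - mean(null)), 2 * sd(null))
})

test_that("searchlight localizes a spatially confined tuned pattern", {
  set.seed(77)
  n <- 120; n_ch <- 12; n_t <- 20
  labels <- runif(n) * 180
  # orientation tuning confined to channels 1-4; positions along a line so
  # neighborhoods are index-contiguous
  u <- c(1, -1, 1, -1, rep(0, 8)); u <- u / sqrt(sum(u^2))
  v <- c(1, 1, -1, -1, rep(0, 8)); v <- v / sqrt(sum(v^2))
  env <- c(rep(0, 4), rep(1, 12), rep(0, 4))
  data <- array(rnorm(n * n_ch * n_t, sd = 0.5), c(n, n_ch, n_t))
  pat <- 3 * (cos(2 * labels * pi / 180) %o% u + sin(2 * labels * pi / 180) %o% v)
  for (j in which(env > 0)) data[, , j] <- data[, , j] + pat
  ep <- as_ori_epochs(data, seq(0, by = 0.02, length.out = n_t), 50,
                      channel_positions = cbind(seq_len(n_ch), 0, 0))
  map <- searchlight_decode(ep, labels, class_bins(4), n_neighbors = 3,
                            window = c(0.1, 0.3), window_len = 3,
                            n_folds = 5, seed = 1)
  expect_equal(nrow(map), n_ch)
  # seed channels overlapping the tuned cluster dominate the map
  expect_gt(min(map$score[1:4]), max(map$score[9:12]))

  # degenerate neighborhood = whole array: every channel gives the
  # whole-array decoding value
  map_all <- searchlight_decode(ep, labels, class_bins(4),
                                n_neighbors = n_ch - 1,
                                window = c(0.1, 0.3), window_len = 3,
                                n_folds = 5, seed = 1)
  expect_equal(max(map_all$score) - min(map_all$score), 0, tolerance = 1e-8)
})
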