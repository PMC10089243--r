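test_that("zero errors give a flat bias curve with zero summed bias", {
  set.seed(1)
  d <- tibble::tibble(err = rep(0, 400), delta = runif(400, -90, 90))
  curve <- bias_curve(d, err, delta)
  expect_equal(nrow(curve), 32)
  expect_true(all(curve$mean == 0))
  expect_equal(summed_bias(curve), 0)
})

test_that("64 raw bins fold into 32 bins at mirrored centers", {
  set.seed(2)
  d <- tibble::tibble(err = rnorm(300), delta = runif(300, -90, 90))
  curve <- bias_curve(d, err, delta)
  raw <- attr(curve, "raw")
  expect_equal(nrow(raw), 64)
  expect_equal(nrow(curve), 32)
  expect_true(all(curve$center > 0 & curve$center < 90))
  # fold identity: folded mean = (raw at +c - raw at -c) / 2
  for (k in c(1, 10, 32)) {
    c_k <- curve$center[k]
    expect_equal(curve$mean[k],
                 0.5 * (raw$mean[raw$center == c_k] -
                          raw$mean[raw$center == -c_k]))
  }
  expect_equal(summed_bias(curve), sum(curve$mean))
  # every raw bin holds round(0.25 n) trials
  expect_equal(unique(raw$n_per_bin), round(0.25 * 300))
})

test_that("quantile-bin membership matches brute-force enumeration at small n", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(8:12, 1)
    deltas <- runif(n, -90, 90)
    m <- sample(1:4, 1)
    center <- runif(1, -90, 90)
    expect_equal(sort(serialbias:::nearest_delta_trials(deltas, center, m)),
                 oracle_bin_members(deltas, center, m))
  }
})

test_that("bias curve is equivariant under joint sign flips", {
  set.seed(4)
  d <- tibble::tibble(delta = runif(500, -90, 90))
  d$err <- dog_bias(d$delta, 2, 30) + rnorm(500, sd = 3)
  c1 <- bias_curve(d, err, delta)
  c2 <- bias_curve(dplyr::mutate(d, err = -err, delta = -delta), err, delta)
  expect_equal(c1$mean, c2$mean, tolerance = 1e-12)
  expect_equal(summed_bias(c1), summed_bias(c2), tolerance = 1e-12)
})

test_that("noiseless DoG responses recover the window-averaged DoG curve", {
  # with bins holding 25% of uniformly distributed deltas, each bin is a
  # +/-22.5 deg moving average of the bias; the analytic windowed DoG is
  # the exact oracle for the expected folded curve
  withr::with_seed(5, {
    n <- 4000
    deltas <- runif(n, -90, 90)
    d <- tibble::tibble(delta = deltas, err = dog_bias(deltas, 3, 25))
  })
  curve <- bias_curve(d, err, delta)
  k <- 3 * exp(0.5) / 25
  half <- 0.25 * 180 / 2   # quantile-bin half-width for uniform deltas
  smoothed <- function(c0) {
    k * 625 / (2 * half) *
      (exp(-(c0 - half)^2 / 1250) - exp(-(c0 + half)^2 / 1250))
  }
  expect_lt(max(abs(curve$mean - smoothed(curve$center))), 0.1)
  expect_lt(abs(summed_bias(curve) - sum(smoothed(curve$center))), 1)
})

test_that("summed bias is null-calibrated when errors are independent of deltas", {
  set.seed(6)
  sims <- replicate(1000, {
    d <- tibble::tibble(err = rnorm(64, sd = 10), delta = runif(64, -90, 90))
    summed_bias(bias_curve(d, err, delta))
  })
  expect_lt(abs(mean(sims)), 2 * sd(sims) / sqrt(length(sims)))
})

test_that("degenerate bias-curve inputs are rejected", {
  d <- tibble::tibble(err = rnorm(6), delta = runif(6, -90, 90))
  expect_error(bias_curve(d, err, delta), "8 trials")
  d2 <- tibble::tibble(err = rnorm(50), delta = rep(10, 50))
  expect_error(bias_curve(d2, err, delta), "identical")
})

test_that("mixture EM identifies pure guessing", {
  withr::with_seed(7, {
    d <- tibble::tibble(e_t = circular_error(runif(1000) * 180, runif(1000) * 180))
  })
  fit <- fit_mixture(d, e_t)
  expect_gt(fit$p["p_guess"], 0.95)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))  # monotone EM
})

test_that("mixture EM recovers a concentrated target component", {
  withr::with_seed(8, {
    d <- tibble::tibble(e_t = serialbias:::rvonmises(1000, 8) * 90 / pi)
  })
  fit <- fit_mixture(d, e_t)
  expect_gte(fit$p["p_target"], 0.95)
  expect_equal(fit$kappa, 8, tolerance = 0.15 * 8)
  expect_equal(rowSums(as.matrix(fit$weights)), rep(1, 1000), tolerance = 1e-9)
})

test_that("mixture EM recovers a small swap rate from generated data", {
  tr <- simulate_trials(4000, 50, c(.5, 0, .5, 0), seed = 9)
  tr <- simulate_responses(tr, behavior_params(kappa = 8, p_target = 0.917,
                                               p_guess = 0.05, p_swap = 0.033),
                           seed = 9)
  d <- dplyr::mutate(tr,
                     e_t = circular_error(response, target_ori),
                     e_nt = circular_error(response, nontarget_ori))
  fit <- fit_mixture(d, e_t, e_nt)
  expect_lt(abs(fit$p["p_swap"] - 0.033), 0.02)
  expect_lt(abs(fit$p["p_target"] - 0.917), 0.05)
})
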