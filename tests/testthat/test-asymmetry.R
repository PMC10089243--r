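mk_sel <- function(trial, delta) {
  tibble::tibble(trial = trial, delta = delta,
                 sign = ifelse(delta > 0, 1, -1),
                 selected = TRUE, reason = NA_character_)
}

mk_rel <- function(ev_by_trial, times = c(0.3, 0.4)) {
  offs <- c(-72, -54, -36, -18, 0, 18, 36, 54, 72, 90)
  n <- nrow(ev_by_trial)
  a <- array(NA_real_, c(n, 10, length(times)))
  for (t in seq_along(times)) a[, , t] <- ev_by_trial
  structure(list(evidence = a, offsets = offs, times = times,
                 trial_ids = seq_len(n), dropped_trials = integer(0)),
            class = "ori_relevidence")
}

test_that("inducer selection applies range, sign and exclusion rules", {
  tr <- simulate_trials(200, 50, c(.5, 0, .5, 0), seed = 30)
  sel <- select_inducer_trials(tr, "same_trial_other_grating")
  d <- circular_error(tr$ori1, tr$ori2)
  expect_equal(sel$selected, abs(d) > 10 & abs(d) < 50)
  expect_equal(sel$sign[sel$selected], ifelse(d[sel$selected] > 0, 1, -1))
  # previous-target inducer: first trial of each block excluded
  sel_b <- select_inducer_trials(tr, "prev_trial_target")
  firsts <- tr$trial[!duplicated(tr$block)]
  expect_true(all(sel_b$reason[sel_b$trial %in% firsts] == "first_of_block"))
  expect_true(all(!sel_b$selected[sel_b$trial %in% firsts]))
  # between-trial range is 0 < |delta| <= 60
  dd <- circular_error(tr$prev_target_ori, tr$ori2)
  expect_equal(sel_b$selected, !is.na(dd) & abs(dd) > 0 & abs(dd) <= 60)
})

test_that("zero-delta trials are excluded (no CW/CCW sign)", {
  tr <- simulate_trials(40, 40, c(1, 0, 0, 0), seed = 31)
  tr$ori1[5] <- tr$ori2[5]   # exact zero delta
  sel <- select_inducer_trials(tr, "same_trial_other_grating",
                               delta_range = c(0, 90), lo_open = FALSE,
                               hi_open = FALSE)
  expect_equal(sel$reason[5], "zero_delta")
  expect_false(sel$selected[5])
})

test_that("selection aborts when a sign group is empty", {
  tr <- simulate_trials(40, 40, c(1, 0, 0, 0), seed = 32)
  tr$ori1 <- wrap_ori(tr$ori2 + 30)   # all deltas exactly +30
  expect_error(select_inducer_trials(tr, "same_trial_other_grating"),
               "sign group")
})

test_that("asymmetry arithmetic matches a brute-force oracle", {
  # two trials with hand-built 10-bin evidence, one per sign group
  ev <- rbind(seq(0.1, 1, by = 0.1), c(0.3, 0.1, 0.4, 0.1, 0.5, 0.9, 0.2, 0.6, 0.5, 0.3))
  rel <- mk_rel(ev)
  sel <- mk_sel(1:2, c(-20, 35))
  res <- asymmetry_score(rel, sel, window = c(0.3, 0.4))
  # oracle: cw bins are offsets -72..-18 (columns 1:4), ccw 18..72 (6:9)
  a1 <- mean(ev[1, 1:4]) - mean(ev[1, 6:9])
  a2 <- mean(ev[2, 1:4]) - mean(ev[2, 6:9])
  expect_equal(res$timecourse$asym_cw, rep(a1, 2))
  expect_equal(res$timecourse$asym_ccw, rep(a2, 2))
  expect_equal(res$timecourse$neural_bias, rep(a1 - a2, 2))
  expect_equal(res$window_mean, a1 - a2)
  expect_equal(res$trial_scores$trial_asym, c(a1, a2))
})

test_that("neural bias is antisymmetric under CW/CCW relabeling and shift-invariant", {
  set.seed(33)
  ev <- matrix(rnorm(8 * 10), 8, 10)
  rel <- mk_rel(ev)
  sel <- mk_sel(1:8, c(-30, -20, -10.5, -40, 15, 25, 35, 45))
  r1 <- asymmetry_score(rel, sel, window = c(0.3, 0.4))
  sel_swapped <- dplyr::mutate(sel, delta = -delta, sign = -sign)
  r2 <- asymmetry_score(rel, sel_swapped, window = c(0.3, 0.4))
  expect_equal(r1$timecourse$neural_bias, -r2$timecourse$neural_bias)
  expect_equal(r1$window_mean, -r2$window_mean)
  # adding a constant to every evidence bin changes nothing
  r3 <- asymmetry_score(mk_rel(ev + 5), sel, window = c(0.3, 0.4))
  expect_equal(r3$timecourse$neural_bias, r1$timecourse$neural_bias)
})

test_that("an injected repulsive encoding shift yields a negative neural bias", {
  sim <- sim_within_experiment(n_trials = 250, shift = 12, seed = 34,
                               snr = 3, n_folds = 5)
  sel <- select_inducer_trials(sim$trials, "same_trial_other_grating")
  rel <- align_evidence(sim$evidence, sim$presented)
  res <- asymmetry_score(rel, sel)
  expect_lt(res$window_mean, 0)
})

test_that("a negative lingering trace yields negative cross-decoding evidence", {
  scores <- sapply(1:5, function(s) {
    sim <- sim_within_experiment(n_trials = 250, seed = 40 + s, snr = 2,
                                 linger = -1, n_folds = 5)
    cs <- cross_decode_evidence(sim$evidence, sim$trials$prev_target_ori)
    window_mean(cs)
  })
  expect_lt(mean(scores), 0)
  # first-of-block trials are dropped by the alignment
  sim <- sim_within_experiment(n_trials = 100, seed = 50, n_folds = 5)
  cs <- cross_decode_evidence(sim$evidence, sim$trials$prev_target_ori)
  expect_equal(nrow(cs), sum(!is.na(sim$trials$prev_target_ori)))
})
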