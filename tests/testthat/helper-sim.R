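# Shared fixtures and independent oracles, built in code at test time.

# Kuiper uniformity test on the doubled-angle circle; returns the p-value.
# Independent of any package code: direct implementation of the statistic
# V = D+ + D- and its asymptotic tail series.
kuiper_p_doubled <- function(ori_deg) {
  u <- sort((2 * ori_deg * pi / 180) %% (2 * pi)) / (2 * pi)
  n <- length(u)
  i <- seq_len(n)
  v <- max(i / n - u) + max(u - (i - 1) / n)
  vs <- v * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  k <- 1:50
  p <- 2 * sum((4 * k^2 * vs^2 - 1) * exp(-2 * k^2 * vs^2))
  min(max(p, 0), 1)
}

# small, fast neural configuration used across decoding tests
test_neural_params <- function(snr = 2, noise_sd = 1, ..., seed = 1) {
  neural_params(n_channels = 16, sfreq = 50, t_start = -0.1, t_end = 0.7,
                signal_onset = 0.05, signal_peak = 0.3, signal_offset = 0.65,
                snr = snr, noise_sd = noise_sd, seed = seed, ...)
}

# one simulated within-trial experiment: all two-item trials, grating-2
# decoding; returns trial table, evidence tensor and presented orientations
sim_within_experiment <- function(n_trials = 250, shift = 0, seed = 1,
                                  snr = 2, linger = 0, n_folds = 10) {
  trials <- simulate_trials(n_trials, 50, c(0.5, 0, 0.5, 0), seed = seed)
  np <- test_neural_params(repulse_shift = shift, linger_amp = linger,
                           snr = snr, seed = seed + 10000L)
  epochs <- simulate_epochs(trials, np, "grating2")
  feats <- build_features(epochs, window_len = 4)
  ev <- decode_cv(feats, trials$ori2, class_bins(10), n_folds = n_folds,
                  seed = seed)
  list(trials = trials, evidence = ev, presented = trials$ori2)
}

# brute-force enumeration oracle for quantile-bin membership: the m trials
# whose wrapped distance to the bin center is smallest, ties by trial order
oracle_bin_members <- function(deltas, center, m) {
  d <- abs(circular_error(deltas, center))
  ranked <- order(d, seq_along(deltas))
  sort(ranked[seq_len(m)])
}

# brute-force run-length cluster scan
oracle_clusters <- function(t, thr) {
  above <- t > thr | t < -thr
  segs <- list()
  start <- NA
  sgn <- 0
  for (i in seq_along(t)) {
    s_i <- if (t[i] > thr) 1 else if (t[i] < -thr) -1 else 0
    if (s_i != 0 && (is.na(start) || s_i != sgn)) {
      if (!is.na(start)) segs[[length(segs) + 1]] <- c(start, i - 1)
      start <- i; sgn <- s_i
    } else if (s_i == 0 && !is.na(start)) {
      segs[[length(segs) + 1]] <- c(start, i - 1)
      start <- NA; sgn <- 0
    }
  }
  if (!is.na(start)) segs[[length(segs) + 1]] <- c(start, length(t))
  do.call(rbind, lapply(segs, function(s) {
    c(start = s[1], end = s[2], mass = sum(t[s[1]:s[2]]))
  }))
}

# one within-trial neural-bias experiment: returns the asymmetry result
# (and optionally the sign-flip z) for a given injected encoding shift
sim_neural_bias <- function(shift, seed, n_trials = 250, snr = 2,
                            n_folds = 5, z_iter = 0) {
  sim <- sim_within_experiment(n_trials = n_trials, shift = shift,
                               seed = seed, snr = snr, n_folds = n_folds)
  sel <- select_inducer_trials(sim$trials, "same_trial_other_grating")
  rel <- align_evidence(sim$evidence, sim$presented)
  asym <- asymmetry_score(rel, sel)
  z <- if (z_iter > 0) {
    signflip_null(list(asym$trial_scores), neural_bias_stat,
                  n_iter = z_iter, seed = seed)$z
  } else NA_real_
  list(window_mean = asym$window_mean, z = z)
}

# one simulated subject for the cross-decoding mechanism: a lingering
# (sign-reversed when linger < 0) previous-target trace of subject-specific
# strength; returns between-trial neural bias and cross-decoding score
sim_cross_subject <- function(linger, seed, n_trials = 250, n_folds = 5) {
  sim <- sim_within_experiment(n_trials = n_trials, seed = seed, snr = 2,
                               linger = linger, n_folds = n_folds)
  cross <- window_mean(cross_decode_evidence(sim$evidence,
                                             sim$trials$prev_target_ori))
  sel <- select_inducer_trials(sim$trials, "prev_trial_target")
  asym <- asymmetry_score(align_evidence(sim$evidence, sim$presented), sel)
  c(cross = cross, bias = asym$window_mean)
}
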