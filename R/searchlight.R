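#' Sensor searchlight decoding map
#'
#' Localizes decodable orientation information across the sensor array: for
#' each channel, decoding is re-run on that channel plus its
#' `n_neighbors` nearest neighbors (Euclidean distance on sensor
#' positions), and the cosine evidence aligned to the presented orientation
#' is averaged over trials and an analysis time window. The conventional
#' whole-array analysis uses a 48-sensor neighborhood (each sensor plus its
#' 47 closest neighbors).
#'
#' @param epochs An `ori_epochs` object with channel positions.
#' @param labels Orientation in degrees per trial.
#' @param bins A [class_bins()] object.
#' @param n_neighbors Number of neighboring channels added to each seed
#'   channel; the neighborhood size is `n_neighbors + 1`.
#' @param window Analysis time window in seconds.
#' @param align_to Orientations used for evidence alignment; defaults to
#'   `labels`.
#' @param window_len,scale Passed to [build_features()].
#' @param n_folds,var_kept,seed Passed to [decode_cv()].
#' @return A tibble with one row per channel: `channel`, `score`,
#'   `n_in_neighborhood`.
#' @export
searchlight_decode <- function(epochs, labels, bins = class_bins(),
                               n_neighbors = 47, window = c(0.25, 0.6),
                               align_to = NULL, window_len = 5,
                               scale = c(gradiometer = 1, magnetometer = 20,
                                         generic = 1),
                               n_folds = 10, var_kept = 0.90, seed = 1) {
  stopifnot(inherits(epochs, "ori_epochs"))
  if (is.null(epochs$channel_positions)) {
    abort("`epochs` has no channel positions; searchlight needs them.")
  }
  n_ch <- dim(epochs$data)[2]
  if (n_neighbors + 1 > n_ch) {
    abort("neighborhood size exceeds the number of channels.")
  }
  align_to <- align_to %||% labels
  dmat <- as.matrix(stats::dist(epochs$channel_positions))
  scores <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    nb <- order(dmat[ch, ], seq_len(n_ch))[seq_len(n_neighbors + 1)]
    sub <- as_ori_epochs(
      epochs$data[, nb, , drop = FALSE], epochs$times, epochs$sfreq,
      epochs$channel_names[nb], epochs$channel_types[nb],
      epochs$channel_positions[nb, , drop = FALSE], epochs$trial_ids
    )
    feats <- build_features(sub, window_len = window_len, scale = scale)
    ev <- decode_cv(feats, labels, bins, n_folds = n_folds,
                    var_kept = var_kept, seed = seed)
    cs <- cosine_evidence(align_evidence(ev, align_to))
    scores[ch] <- window_mean(cs, window)
  }
  tibble(channel = epochs$channel_names, score = scores,
         n_in_neighborhood = n_neighbors + 1)
}
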