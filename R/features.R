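#' Sliding-window spatiotemporal features
#'
#' Concatenates all channels across a trailing sliding window of
#' `window_len` samples into one feature vector per trial and time point,
#' after scaling each channel by a factor determined by its type (used to
#' bring magnetometers onto the gradiometer scale, conventionally x20).
#' The value at time `t` summarizes samples `(t - window_len + 1) ... t`;
#' output time points are restricted to those where the full window exists.
#' No baseline correction is applied, so slow signals from preceding
#' stimuli are retained.
#'
#' @param epochs An `ori_epochs` object.
#' @param window_len Window length in samples (>= 1). 30 samples at 200 Hz
#'   corresponds to the conventional 150 ms window.
#' @param scale Named numeric vector mapping channel type to a
#'   multiplicative factor.
#' @return An object of class `ori_features`: list with `features`
#'   (trials x n_features x n_times array, `n_features = n_channels *
#'   window_len`), `times` (window-end times), `trial_ids`, `window_len`.
#' @examples
#' # 306 channels x 30 samples -> 9180-dimensional features
#' @export
build_features <- function(epochs, window_len = 30,
                           scale = c(gradiometer = 1, magnetometer = 20,
                                     generic = 1)) {
  stopifnot(inherits(epochs, "ori_epochs"))
  d <- dim(epochs$data)
  if (window_len < 1) abort("`window_len` must be >= 1.")
  if (window_len > d[3]) abort("`window_len` exceeds the epoch length.")
  fac <- unname(scale[epochs$channel_types])
  if (anyNA(fac)) abort("`scale` must provide a factor for every channel type present.")
  x <- sweep(epochs$data, 2, fac, `*`)
  n_out <- d[3] - window_len + 1
  feats <- array(NA_real_, dim = c(d[1], d[2] * window_len, n_out))
  for (j in seq_len(n_out)) {
    # column-major flatten: channels vary fastest, then window sample
    feats[, , j] <- matrix(x[, , j:(j + window_len - 1)], nrow = d[1])
  }
  structure(
    list(features = feats,
         times = epochs$times[window_len:d[3]],
         trial_ids = epochs$trial_ids,
         window_len = window_len),
    class = "ori_features"
  )
}

#' @export
print.ori_features <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<ori_features> %d trials x %d features x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}
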