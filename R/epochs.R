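#' Epoched multichannel data container
#'
#' A minimal container for epoched recordings: a numeric array of dimension
#' trials x channels x time plus the time axis, sampling rate and channel
#' metadata. Construct with `as_ori_epochs()` from an array (e.g. one
#' exported from another epochs format), or let [simulate_epochs()] build
#' one. `tidy()` converts to a long tibble.
#'
#' @param data Numeric array, trials x channels x time, all finite.
#' @param times Numeric vector of sample times in seconds; strictly
#'   increasing and uniformly spaced at `1/sfreq`.
#' @param sfreq Sampling rate in Hz.
#' @param channel_names Character vector, one per channel. Defaults to
#'   `"CH001"`, ...
#' @param channel_types Character vector per channel; one of
#'   `"gradiometer"`, `"magnetometer"`, `"generic"`. Defaults to
#'   `"generic"`.
#' @param channel_positions Numeric channels x 3 matrix of sensor positions
#'   (arbitrary units) or `NULL`; required by [searchlight_decode()].
#' @param trial_ids Integer identifiers linking epochs to trial-table rows;
#'   defaults to `1:n_trials`.
#' @param info Optional named list of provenance (e.g. generator
#'   parameters).
#' @return An object of class `ori_epochs`.
#' @export
as_ori_epochs <- function(data, times, sfreq,
                          channel_names = NULL,
                          channel_types = NULL,
                          channel_positions = NULL,
                          trial_ids = NULL,
                          info = list()) {
  if (length(dim(data)) != 3) abort("`data` must be a trials x channels x time array.")
  if (!all(is.finite(data))) abort("`data` contains non-finite samples.")
  n_ch <- dim(data)[2]
  n_t <- dim(data)[3]
  if (length(times) != n_t) abort("`times` length must match dim(data)[3].")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / sfreq)) > 1e-6) {
    abort("`times` must be strictly increasing and uniformly spaced at 1/sfreq.")
  }
  channel_names <- channel_names %||% sprintf("CH%03d", seq_len(n_ch))
  channel_types <- channel_types %||% rep("generic", n_ch)
  if (length(channel_names) != n_ch || length(channel_types) != n_ch) {
    abort("channel metadata length must match dim(data)[2].")
  }
  if (!all(channel_types %in% c("gradiometer", "magnetometer", "generic"))) {
    abort("`channel_types` must be gradiometer, magnetometer or generic.")
  }
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    if (nrow(channel_positions) != n_ch || ncol(channel_positions) != 3) {
      abort("`channel_positions` must be a channels x 3 matrix.")
    }
  }
  trial_ids <- as.integer(trial_ids %||% seq_len(dim(data)[1]))
  if (length(trial_ids) != dim(data)[1]) {
    abort("`trial_ids` length must match dim(data)[1].")
  }
  structure(
    list(data = data, times = as.numeric(times), sfreq = sfreq,
         channel_names = channel_names, channel_types = channel_types,
         channel_positions = channel_positions, trial_ids = trial_ids,
         info = info),
    class = "ori_epochs"
  )
}

#' @export
print.ori_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ori_epochs> %d trials x %d channels x %d samples (%.0f Hz, %.3f..%.3f s)\n",
    d[1], d[2], d[3], x$sfreq, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.ori_epochs <- function(x) dim(x$data)

#' Tidy an epochs object into a long tibble
#'
#' @param x An `ori_epochs` object.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `time`, `value`.
#' @export
tidy.ori_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(x$trial_ids, times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Write / read epochs as a plain-text container
#'
#' Serializes an `ori_epochs` object to `<path>.csv` (long format:
#' trial, channel index, time index, value) plus a JSON sidecar
#' `<path>.json` holding the time axis, sampling rate, channel metadata and
#' any generation parameters. Plain text keeps runs portable and
#' diff-friendly; use it for desk-scale data only.
#'
#' @param x An `ori_epochs` object.
#' @param path Base path (without extension).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an `ori_epochs` object.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "ori_epochs"))
  d <- dim(x$data)
  long <- data.frame(
    trial = rep(x$trial_ids, times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
  utils::write.csv(long, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(
    n_trials = d[1], n_channels = d[2], n_times = d[3],
    times = x$times, sfreq = x$sfreq,
    channel_names = x$channel_names, channel_types = x$channel_types,
    channel_positions = x$channel_positions, trial_ids = x$trial_ids,
    info = x$info
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(path, ".csv"))
  a <- array(NA_real_, dim = c(meta$n_trials, meta$n_channels, meta$n_times))
  tr <- match(long$trial, meta$trial_ids)
  a[cbind(tr, long$channel, long$sample)] <- long$value
  pos <- meta$channel_positions
  if (!is.null(pos)) pos <- matrix(unlist(pos), ncol = 3)
  as_ori_epochs(a, meta$times, meta$sfreq, meta$channel_names,
                meta$channel_types, pos, meta$trial_ids,
                info = as.list(meta$info))
}
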