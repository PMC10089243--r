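#' Folded performance-bias curve and summed bias
#'
#' Expresses the mean signed report error as a function of the signed
#' angular distance between an inducer orientation and the target
#' (`delta = circular_error(inducer, target)`, so positive delta means the
#' inducer lies clockwise of the target and an attractive bias appears as
#' positive bin means at positive deltas). Deltas are binned into
#' `n_bins_raw` equally sized, overlapping bins: bin i is centered at
#' `c_i = -90 + (i + 0.5) * 180 / n_bins_raw` (half-step offset, so no
#' center sits at 0 or +/-90 and mirror pairs fold exactly) and contains
#' the `round(bin_frac * n)` trials whose wrapped distance `|delta - c_i|`
#' is smallest, with ties broken by trial order. The error sign is flipped
#' in negative-center bins, mirrored center pairs are averaged, and the
#' resulting folded curve over (0, 90) is summarized by the summed bias —
#' the sum of the folded bin means, positive for attraction and negative
#' for repulsion.
#'
#' For between-trial inducers, drop the first trial of each block before
#' calling (see [select_inducer_trials()] or filter on
#' `is.na(prev_target_ori)`).
#'
#' @param data A data frame with one row per trial.
#' @param error Column of signed report errors in degrees (-90, 90].
#' @param delta Column of signed inducer-minus-target distances in degrees.
#' @param n_bins_raw Number of raw overlapping bins (even). Default 64.
#' @param bin_frac Fraction of trials per bin. Default 0.25.
#' @return A tibble of class `tbl_biascurve` with one row per folded bin:
#'   `bin`, `center` (degrees in (0, 90)), `mean` (degrees), `n_per_bin`;
#'   attributes `summed_bias` (degrees), `raw` (the 64-bin unfolded
#'   tibble), `n_trials`. `glance()` extracts the scalar summary.
#' @examples
#' trials <- simulate_trials(n_trials = 400, seed = 2) |>
#'   simulate_responses(behavior_params(), seed = 2)
#' curve <- trials |>
#'   dplyr::filter(!is.na(prev_target_ori)) |>
#'   dplyr::mutate(err = circular_error(response, target_ori),
#'                 d = circular_error(prev_target_ori, target_ori)) |>
#'   bias_curve(err, d)
#' glance(curve)
#' @export
bias_curve <- function(data, error, delta, n_bins_raw = 64, bin_frac = 0.25) {
  err <- eval_tidy(enquo(error), data)
  dlt <- eval_tidy(enquo(delta), data)
  n <- length(err)
  if (length(dlt) != n) abort("`error` and `delta` must have equal length.")
  if (anyNA(err) || anyNA(dlt)) abort("missing values in `error` or `delta`; filter them first.")
  if (n < 8) abort("at least 8 trials are required.")
  if (n_bins_raw < 2 || n_bins_raw %% 2 != 0) abort("`n_bins_raw` must be even and >= 2.")
  m <- round(bin_frac * n)
  if (m < 1) abort("`bin_frac` leaves no trials per bin.")
  if (length(unique(dlt)) == 1) abort("all deltas identical; binning is degenerate.")

  centers_raw <- -90 + (seq_len(n_bins_raw) - 0.5) * 180 / n_bins_raw
  raw_means <- vapply(centers_raw, function(c0) {
    idx <- nearest_delta_trials(dlt, c0, m)
    mean(err[idx])
  }, numeric(1))

  neg <- centers_raw < 0
  folded_centers <- centers_raw[!neg]
  # flip the error sign in negative-center bins, then average mirror pairs
  folded <- 0.5 * (raw_means[!neg] + (-raw_means)[rev(which(neg))])

  out <- tibble(
    bin = seq_along(folded_centers),
    center = folded_centers,
    mean = folded,
    n_per_bin = m
  )
  attr(out, "raw") <- tibble(center = centers_raw, mean = raw_means,
                             n_per_bin = m)
  attr(out, "summed_bias") <- sum(folded)
  attr(out, "n_trials") <- n
  class(out) <- c("tbl_biascurve", class(out))
  out
}

# indices of the m trials with smallest wrapped |delta - center|,
# deterministic tie-break by trial order
nearest_delta_trials <- function(deltas, center, m) {
  d <- abs(circular_error(deltas, center))
  order(d, seq_along(d))[seq_len(m)]
}

#' @rdname bias_curve
#' @param x A `tbl_biascurve` object.
#' @param ... Unused.
#' @export
glance.tbl_biascurve <- function(x, ...) {
  tibble(summed_bias = attr(x, "summed_bias"),
         n_trials = attr(x, "n_trials"),
         n_bins = nrow(x),
         n_per_bin = x$n_per_bin[1])
}

#' @rdname bias_curve
#' @export
summed_bias <- function(x) {
  stopifnot(inherits(x, "tbl_biascurve"))
  attr(x, "summed_bias")
}

#' Plot a folded bias curve
#'
#' @param object A `tbl_biascurve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbl_biascurve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "absolute inducer–target distance (deg)",
      y = "bias (deg)",
      subtitle = sprintf("summed bias = %.2f°", attr(object, "summed_bias"))
    )
}
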