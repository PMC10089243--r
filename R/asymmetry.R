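#' Neural asymmetry and bias scores
#'
#' Quantifies attractive versus repulsive shifts of the decoded
#' representation relative to an inducer orientation. For evidence aligned
#' to the presented orientation, each trial's asymmetry is the mean
#' evidence over the clockwise offset bins (-72 to -18 deg) minus the mean
#' over the counterclockwise bins (18 to 72 deg); the 0 and 90 deg offsets
#' belong to neither set. Group asymmetry time courses are averaged
#' separately for trials with CW inducers (`sign == -1` in the selection)
#' and CCW inducers, and the neural bias score is their difference,
#' CW-group minus CCW-group: positive values indicate an attractive shift
#' toward the inducer, negative values a repulsive shift away from it.
#'
#' @param rel An `ori_relevidence` object aligned to the presented
#'   orientation.
#' @param sel A selection tibble from [select_inducer_trials()].
#' @param window Analysis window in seconds for the scalar summary.
#' @param cw_offsets,ccw_offsets Offset bins (degrees) averaged for each
#'   side.
#' @return An object of class `asym_result`: `timecourse` (tibble with
#'   `time`, `asym_cw`, `asym_ccw`, `neural_bias`), `window_mean`,
#'   `n_cw`, `n_ccw`, `window`, and `trial_scores` (tibble with `trial`,
#'   `sign`, `trial_asym` = the per-trial window-averaged asymmetry, the
#'   input to sign-flip nulls). `tidy()` returns the time courses,
#'   `glance()` the scalar summary.
#' @export
asymmetry_score <- function(rel, sel, window = c(0.25, 0.6),
                            cw_offsets = c(-72, -54, -36, -18),
                            ccw_offsets = c(18, 36, 54, 72)) {
  stopifnot(inherits(rel, "ori_relevidence"))
  if (length(cw_offsets) == 0 || length(ccw_offsets) == 0) {
    abort("`cw_offsets` and `ccw_offsets` must be non-empty.")
  }
  cw_ix <- match(cw_offsets, rel$offsets)
  ccw_ix <- match(ccw_offsets, rel$offsets)
  if (anyNA(cw_ix) || anyNA(ccw_ix)) {
    abort("offset bins not present in the aligned evidence.")
  }
  keep <- sel[sel$selected & sel$trial %in% rel$trial_ids, , drop = FALSE]
  if (nrow(keep) == 0) abort("no selected trials are present in the evidence.")
  rows <- match(keep$trial, rel$trial_ids)

  # per-trial asymmetry time course: mean CW-bin minus mean CCW-bin evidence
  a <- apply(rel$evidence[rows, cw_ix, , drop = FALSE], c(1, 3), mean) -
    apply(rel$evidence[rows, ccw_ix, , drop = FALSE], c(1, 3), mean)

  cw_g <- keep$sign == -1
  ccw_g <- keep$sign == 1
  if (!any(cw_g) || !any(ccw_g)) abort("both sign groups must be represented.")
  asym_cw <- colMeans(a[cw_g, , drop = FALSE])
  asym_ccw <- colMeans(a[ccw_g, , drop = FALSE])
  nb <- asym_cw - asym_ccw

  in_win <- rel$times >= window[1] & rel$times <= window[2]
  if (!any(in_win)) abort("no time points fall inside `window`.")
  trial_asym <- rowMeans(a[, in_win, drop = FALSE])

  structure(
    list(
      timecourse = tibble(time = rel$times, asym_cw = asym_cw,
                          asym_ccw = asym_ccw, neural_bias = nb),
      window_mean = mean(nb[in_win]),
      n_cw = sum(cw_g), n_ccw = sum(ccw_g), window = window,
      trial_scores = tibble(trial = keep$trial, sign = keep$sign,
                            delta = keep$delta, trial_asym = trial_asym)
    ),
    class = "asym_result"
  )
}

#' @export
print.asym_result <- function(x, ...) {
  cat(sprintf(
    "<asym_result> neural bias window mean = %+.4f (%.0f-%.0f ms; CW n=%d, CCW n=%d)\n",
    x$window_mean, x$window[1] * 1000, x$window[2] * 1000, x$n_cw, x$n_ccw))
  invisible(x)
}

#' @rdname asymmetry_score
#' @param x An `asym_result` object.
#' @param ... Unused.
#' @export
tidy.asym_result <- function(x, ...) x$timecourse

#' @rdname asymmetry_score
#' @export
glance.asym_result <- function(x, ...) {
  tibble(window_mean = x$window_mean, n_cw = x$n_cw, n_ccw = x$n_ccw,
         window_start = x$window[1], window_end = x$window[2])
}

#' Plot asymmetry and neural-bias time courses
#'
#' @param object An `asym_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asym_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$timecourse, -"time",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::annotate("rect", xmin = object$window[1], xmax = object$window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "evidence difference")
}

#' Cross-decoding evidence for the previous trial's target
#'
#' Aligns a class-evidence tensor (from a classifier trained on the
#' presented orientation) to each trial's previous-trial target and
#' convolves with a cosine. First-of-block trials (undefined previous
#' target) are dropped by the alignment. Negative window means indicate a
#' sign-reversed lingering trace of the previous target.
#'
#' @param ev An `ori_evidence` object.
#' @param prev_target Previous-trial target orientation per trial (degrees;
#'   `NA` drops the trial).
#' @return An `ori_cosine` trials x time matrix (see [cosine_evidence()]).
#' @export
cross_decode_evidence <- function(ev, prev_target) {
  cosine_evidence(align_evidence(ev, prev_target))
}
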