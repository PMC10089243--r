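#' Align class evidence to a per-trial reference orientation
#'
#' Re-indexes the class axis of an evidence tensor so that offset 0 is the
#' class bin containing each trial's alignment orientation, producing a
#' representational-similarity curve per trial and time point. With 10
#' classes the relative offsets are -72, -54, ..., 72, 90 degrees
#' (class-center minus alignment-bin-center, wrapped to (-90, 90]).
#' Alignment is a pure permutation of the class axis per trial. Trials with
#' an undefined aligner (e.g. first-of-block when aligning to the previous
#' target) are dropped and recorded.
#'
#' Use `align_to = ` the presented orientation for standard decoding curves
#' and the previous trial's target for cross-decoding.
#'
#' @param ev An `ori_evidence` object.
#' @param align_to Orientation in degrees per trial (length = n trials in
#'   `ev`); `NA` drops the trial.
#' @return An object of class `ori_relevidence`: `evidence`
#'   (trials x offsets x time), `offsets`, `times`, `trial_ids`,
#'   `dropped_trials`.
#' @export
align_evidence <- function(ev, align_to) {
  stopifnot(inherits(ev, "ori_evidence"))
  d <- dim(ev$evidence)
  if (length(align_to) != d[1]) {
    abort("`align_to` must have one orientation per trial of the evidence tensor.")
  }
  keep <- !is.na(align_to)
  if (!any(keep)) abort("all alignment orientations are missing.")
  bins <- ev$bins
  k <- bins$n_classes
  # offsets for alignment class a: center_j - center_a wrapped to (-90, 90]
  offsets <- sort(circular_error(bins$centers, bins$centers[1]))
  a_cls <- ori_class(align_to[keep], bins)
  sub <- ev$evidence[keep, , , drop = FALSE]
  out <- array(NA_real_, dim = c(sum(keep), k, d[3]))
  for (i in seq_len(sum(keep))) {
    off_i <- circular_error(bins$centers, bins$centers[a_cls[i]])
    perm <- order(off_i)             # class indices sorted by their offset
    out[i, , ] <- sub[i, perm, , drop = FALSE]
  }
  structure(
    list(evidence = out, offsets = offsets, times = ev$times,
         trial_ids = ev$trial_ids[keep],
         dropped_trials = ev$trial_ids[!keep]),
    class = "ori_relevidence"
  )
}

#' @export
print.ori_relevidence <- function(x, ...) {
  d <- dim(x$evidence)
  cat(sprintf("<ori_relevidence> %d trials x %d offsets x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Tidy aligned evidence
#'
#' @param x An `ori_relevidence` object.
#' @param ... Unused.
#' @return Tibble with `trial`, `offset`, `time`, `evidence`.
#' @export
tidy.ori_relevidence <- function(x, ...) {
  d <- dim(x$evidence)
  tibble(
    trial = rep(x$trial_ids, times = d[2] * d[3]),
    offset = rep(rep(x$offsets, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    evidence = as.vector(x$evidence)
  )
}

#' Cosine-convolved classifier evidence
#'
#' Collapses a representational-similarity curve into a single signed
#' evidence score per trial and time point:
#' `score(trial, t) = mean_k evidence(trial, k, t) * cos(2 * offset_k)`.
#' Positive scores indicate evidence concentrated at the aligned
#' orientation; because class evidence is mean-centered, the score is
#' invariant to additive offsets.
#'
#' @param rel An `ori_relevidence` object.
#' @return A trials x time matrix with attributes `times` and `trial_ids`;
#'   class `ori_cosine`.
#' @export
cosine_evidence <- function(rel) {
  stopifnot(inherits(rel, "ori_relevidence"))
  w <- cos(2 * rel$offsets * pi / 180)
  d <- dim(rel$evidence)
  out <- matrix(0, d[1], d[3])
  for (k in seq_len(d[2])) out <- out + rel$evidence[, k, ] * w[k]
  out <- out / d[2]
  structure(out, times = rel$times, trial_ids = rel$trial_ids,
            class = c("ori_cosine", "matrix", "array"))
}

#' Average a trials x time score over a time window
#'
#' @param score An `ori_cosine` matrix (or any trials x time matrix with a
#'   `times` attribute).
#' @param window Two-element numeric window in seconds (inclusive).
#' @param by_trial If `TRUE`, return one mean per trial; otherwise the
#'   grand mean.
#' @return Numeric scalar or per-trial vector.
#' @export
window_mean <- function(score, window = c(0.25, 0.6), by_trial = FALSE) {
  times <- attr(score, "times")
  if (is.null(times)) abort("`score` must carry a `times` attribute.")
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel)) abort("no time points fall inside `window`.")
  m <- rowMeans(score[, sel, drop = FALSE])
  if (by_trial) m else mean(m)
}

#' Tidy a cosine-evidence matrix
#'
#' @param x An `ori_cosine` object.
#' @param ... Unused.
#' @return Tibble with `trial`, `time`, `score`.
#' @export
tidy.ori_cosine <- function(x, ...) {
  tibble(
    trial = rep(attr(x, "trial_ids"), times = ncol(x)),
    time = rep(attr(x, "times"), each = nrow(x)),
    score = as.vector(unclass(x))
  )
}
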