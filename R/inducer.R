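#' Select trials by inducer distance and label their CW/CCW sign
#'
#' Computes the signed circular distance `delta = circular_error(inducer,
#' presented)` between an inducer orientation (same-trial other grating,
#' previous-trial target, or previous-trial nontarget) and the presented
#' orientation under analysis, keeps trials whose absolute distance falls
#' in the behaviorally effective range, and labels each kept trial's
#' inducer as clockwise (CW, `delta < 0`, i.e. the inducer sits at a
#' negative signed offset from the presented orientation) or
#' counterclockwise (CCW, `delta > 0`). Trials with `delta == 0` carry no
#' sign and are excluded, as are trials with an undefined inducer
#' (first-of-block trials for previous-trial inducers, one-item trials for
#' the same-trial inducer) and out-of-range trials.
#'
#' Default ranges follow the behaviorally significant windows: within-trial
#' `10 < |delta| < 50` (both ends open), between-trial `0 < |delta| <= 60`.
#'
#' @param trials A trial table.
#' @param inducer One of `"same_trial_other_grating"`,
#'   `"prev_trial_target"`, `"prev_trial_nontarget"`.
#' @param presented Column (tidy-eval) holding the presented orientation
#'   under analysis; defaults to `ori2` (the second grating).
#' @param delta_range Two-element `c(lo, hi)` in degrees of `|delta|`;
#'   defaults depend on `inducer` (see above).
#' @param lo_open,hi_open Whether the range ends are open; defaults depend
#'   on `inducer`.
#' @return A tibble with one row per input trial: `trial`, `delta`,
#'   `sign` (-1 CW, +1 CCW, `NA` when excluded), `selected`, `reason`
#'   (`NA` for selected trials). Attribute `n_selected` holds the count.
#' @export
select_inducer_trials <- function(trials,
                                  inducer = c("same_trial_other_grating",
                                              "prev_trial_target",
                                              "prev_trial_nontarget"),
                                  presented = NULL,
                                  delta_range = NULL,
                                  lo_open = NULL, hi_open = NULL) {
  inducer <- match.arg(inducer)
  pres_q <- enquo(presented)
  pres <- if (rlang::quo_is_null(pres_q)) trials$ori2 else eval_tidy(pres_q, trials)
  ind <- switch(inducer,
    same_trial_other_grating = trials$ori1,
    prev_trial_target = trials$prev_target_ori,
    prev_trial_nontarget = trials$prev_nontarget_ori
  )
  within <- inducer == "same_trial_other_grating"
  delta_range <- delta_range %||% if (within) c(10, 50) else c(0, 60)
  lo_open <- lo_open %||% TRUE
  hi_open <- hi_open %||% within

  delta <- circular_error(ind, pres)
  undefined <- is.na(delta)
  zero <- !undefined & delta == 0
  lo_ok <- if (lo_open) abs(delta) > delta_range[1] else abs(delta) >= delta_range[1]
  hi_ok <- if (hi_open) abs(delta) < delta_range[2] else abs(delta) <= delta_range[2]
  in_range <- !undefined & !zero & lo_ok & hi_ok
  reason <- dplyr::case_when(
    undefined & inducer != "same_trial_other_grating" &
      trials$trial %in% first_of_block(trials) ~ "first_of_block",
    undefined ~ "undefined",
    zero ~ "zero_delta",
    !in_range ~ "out_of_range",
    TRUE ~ NA_character_
  )
  out <- tibble(
    trial = trials$trial,
    delta = delta,
    sign = ifelse(in_range, ifelse(delta > 0, 1, -1), NA_real_),
    selected = in_range,
    reason = reason
  )
  n_cw <- sum(out$sign == -1, na.rm = TRUE)
  n_ccw <- sum(out$sign == 1, na.rm = TRUE)
  if (n_cw == 0 || n_ccw == 0) {
    abort(sprintf(
      "need selected trials in both sign groups; got CW n=%d, CCW n=%d.",
      n_cw, n_ccw))
  }
  attr(out, "n_selected") <- sum(out$selected)
  attr(out, "inducer") <- inducer
  out
}

first_of_block <- function(trials) {
  trials$trial[!duplicated(trials$block)]
}
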