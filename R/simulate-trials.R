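#' Simulate a trial table for a two-grating orientation recall session
#'
#' Generates the experimental design: per trial, orientations of up to two
#' sequentially presented gratings drawn i.i.d. uniform on [0, 180), a cue
#' indicating which grating must be reported, and the block structure. The
#' four conditions cross cue (report-first / report-second) with item count
#' (two items / one item); on one-item trials only the cued grating is
#' presented. Previous-trial target and nontarget orientations are carried
#' forward within blocks and are `NA` on the first trial of each block.
#'
#' @param n_trials Number of trials (> 0). Default 400.
#' @param block_size Trials per block (the last block may be shorter).
#'   Default 50.
#' @param condition_mix Probabilities of the four conditions, in the order
#'   report-first/two-items, report-first/one-item, report-second/two-items,
#'   report-second/one-item. Must sum to 1. Default balanced.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with columns `trial`, `block`, `ori1`, `ori2`, `cue`,
#'   `n_items`, `target_ori`, `nontarget_ori`, `response` (all `NA`, filled
#'   by [simulate_responses()]), `prev_target_ori`, `prev_nontarget_ori`.
#' @examples
#' trials <- simulate_trials(n_trials = 100, block_size = 50, seed = 1)
#' dplyr::count(trials, cue, n_items)
#' @export
simulate_trials <- function(n_trials = 400,
                            block_size = 50,
                            condition_mix = c(0.25, 0.25, 0.25, 0.25),
                            seed = 1) {
  if (n_trials <= 0) abort("`n_trials` must be > 0.")
  if (block_size <= 0) abort("`block_size` must be > 0.")
  if (length(condition_mix) != 4 || any(condition_mix < 0) ||
      abs(sum(condition_mix) - 1) > 1e-9) {
    abort("`condition_mix` must be 4 non-negative probabilities summing to 1.")
  }
  withr::with_seed(seed, {
    cond <- sample.int(4L, n_trials, replace = TRUE, prob = condition_mix)
    ori1 <- runif(n_trials) * 180
    ori2 <- runif(n_trials) * 180
    cue <- ifelse(cond <= 2L, "report_first", "report_second")
    n_items <- ifelse(cond %in% c(1L, 3L), 2L, 1L)
    # one-item trials present only the cued grating
    ori1[cond == 4L] <- NA_real_
    ori2[cond == 2L] <- NA_real_
    tbl <- tibble(
      trial = seq_len(n_trials),
      block = (seq_len(n_trials) - 1L) %/% as.integer(block_size) + 1L,
      ori1 = ori1,
      ori2 = ori2,
      cue = cue,
      n_items = as.integer(n_items),
      target_ori = ifelse(cue == "report_first", ori1, ori2),
      nontarget_ori = ifelse(cue == "report_first", ori2, ori1),
      response = NA_real_
    )
    tbl <- dplyr::group_by(tbl, .data$block)
    tbl <- dplyr::mutate(
      tbl,
      prev_target_ori = dplyr::lag(.data$target_ori),
      prev_nontarget_ori = dplyr::lag(.data$nontarget_ori)
    )
    dplyr::ungroup(tbl)
  })
}

#' Fill in behavioral responses under a known bias model
#'
#' Draws a response for every trial of a trial table from the mixture model
#' described in [behavior_params()]: with probability `p_target` the response
#' centers on the target (plus systematic biases), with `p_swap` on the
#' same-trial nontarget, and with `p_guess` it is uniform on [0, 180).
#' Von Mises noise with concentration `kappa` (on the doubled-angle circle)
#' is added to target- and swap-component responses unless
#' `params$noiseless` is `TRUE`.
#'
#' The systematic bias on target-component trials is
#' `+DoG(d_between; attract_amp, attract_width)
#'  - DoG(d_within; repulse_amp, repulse_width)`,
#' where `d_between = circular_error(prev_target_ori, target_ori)` (zero
#' contribution on first-of-block trials) and
#' `d_within = circular_error(nontarget_ori, target_ori)` (zero when no
#' nontarget was shown). On trials without a nontarget the swap component is
#' unavailable and its probability mass is reassigned to the target
#' component.
#'
#' @param trials A trial table from [simulate_trials()].
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @return The trial table with `response` filled (degrees in [0, 180)) and
#'   an extra `component` column (`"target"`, `"swap"`, `"guess"`) recording
#'   the latent mixture component, useful for recovery tests.
#' @export
simulate_responses <- function(trials, params = behavior_params(), seed = 1) {
  stopifnot(inherits(params, "behavior_params"))
  if (!all(c("target_ori", "nontarget_ori") %in% names(trials))) {
    abort("`trials` must contain `target_ori` and `nontarget_ori` columns.")
  }
  if (anyNA(trials$target_ori)) {
    abort("every trial must have a `target_ori` before responses can be simulated.")
  }
  n <- nrow(trials)
  withr::with_seed(seed, {
    comp <- sample(c("target", "guess", "swap"), n, replace = TRUE,
                   prob = c(params$p_target, params$p_guess, params$p_swap))
    # swap undefined without a same-trial nontarget -> respond to target
    comp[comp == "swap" & is.na(trials$nontarget_ori)] <- "target"

    d_between <- circular_error(trials$prev_target_ori, trials$target_ori)
    d_between[is.na(d_between)] <- 0
    d_within <- circular_error(trials$nontarget_ori, trials$target_ori)
    d_within[is.na(d_within)] <- 0
    bias <- dog_bias(d_between, params$attract_amp, params$attract_width) -
      dog_bias(d_within, params$repulse_amp, params$repulse_width)

    noise <- if (params$noiseless) {
      numeric(n)
    } else {
      # doubled-angle radians -> orientation degrees
      rvonmises(n, params$kappa) * 90 / pi
    }

    centre <- dplyr::case_when(
      comp == "target" ~ trials$target_ori + bias,
      comp == "swap" ~ trials$nontarget_ori,
      TRUE ~ runif(n) * 180
    )
    resp <- wrap_ori(centre + ifelse(comp == "guess", 0, noise))
    dplyr::mutate(trials, response = resp, component = comp)
  })
}

#' Read and write trial tables as CSV
#'
#' Fixed-header CSV round-trip for trial tables. Missing orientations
#' (absent gratings, first-of-block previous orientations, unanswered
#' trials) are encoded as empty fields; orientations are decimal degrees.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a tibble.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, na.strings = "")
  out$n_items <- as.integer(out$n_items)
  as_tibble(out)
}
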