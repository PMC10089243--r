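#' Trialwise sign-flip shuffle null for bias statistics
#'
#' Builds the permutation null for any statistic that depends on the sign
#' of a per-trial angular distance (summed behavioral bias, neural bias
#' score, ...). On each iteration the `delta` column of every subject's
#' trial table is independently multiplied by random +/-1 per trial, the
#' statistic is recomputed per subject and averaged across subjects. The
#' observed value is the same computation without flips. The null is
#' z-scored; the observed statistic's z-score against the null yields the
#' two-tailed p-value (`p_z`); the empirical tail count with the
#' `(b + 1) / (m + 1)` correction is also reported (`p_perm`).
#'
#' @param subjects A list of per-subject data frames, each with a `delta`
#'   column (signed degrees) plus whatever columns `statistic` uses.
#' @param statistic Function mapping one subject data frame to a scalar;
#'   must be deterministic.
#' @param n_iter Number of sign-flip iterations.
#' @param seed Integer seed.
#' @return An object of class `null_distribution`: `observed`, `z`,
#'   `p_z`, `p_perm`, `null_values`, `n_iter`, `seed`, `n_subjects`.
#' @examples
#' # statistic: neural bias = mean CW-group minus mean CCW-group asymmetry
#' nb_stat <- function(df) {
#'   mean(df$trial_asym[df$delta < 0]) - mean(df$trial_asym[df$delta > 0])
#' }
#' @export
signflip_null <- function(subjects, statistic, n_iter = 10000, seed = 1) {
  if (!is.list(subjects) || length(subjects) < 1) {
    abort("`subjects` must be a non-empty list of per-subject data frames.")
  }
  if (!all(vapply(subjects, function(s) "delta" %in% names(s), logical(1)))) {
    abort("every subject data frame needs a `delta` column.")
  }
  obs_by_subj <- vapply(subjects, statistic, numeric(1))
  if (!all(is.finite(obs_by_subj))) {
    abort("`statistic` returned a non-finite observed value.")
  }
  observed <- mean(obs_by_subj)
  null_values <- numeric(n_iter)
  withr::with_seed(seed, {
    for (b in seq_len(n_iter)) {
      vals <- vapply(subjects, function(s) {
        s$delta <- s$delta * sample(c(-1, 1), nrow(s), replace = TRUE)
        statistic(s)
      }, numeric(1))
      if (!all(is.finite(vals))) {
        abort(sprintf("`statistic` returned a non-finite value at iteration %d.", b))
      }
      null_values[b] <- mean(vals)
    }
  })
  mu <- mean(null_values)
  sg <- sd(null_values)
  if (sg == 0) abort("degenerate null distribution (zero spread).")
  z <- (observed - mu) / sg
  z_null <- (null_values - mu) / sg
  structure(
    list(observed = observed, z = z,
         p_z = 2 * pnorm(-abs(z)),
         p_perm = (sum(abs(z_null) >= abs(z)) + 1) / (n_iter + 1),
         null_values = null_values, n_iter = n_iter, seed = seed,
         n_subjects = length(subjects)),
    class = "null_distribution"
  )
}

#' Neural-bias statistic for sign-flip nulls
#'
#' The subject-level statistic behind the neural bias score, in the form
#' [signflip_null()] expects: given a data frame with `delta` and
#' `trial_asym` columns (see the `trial_scores` element of
#' [asymmetry_score()]), returns the mean per-trial asymmetry over
#' CW-inducer trials (`delta < 0`) minus the mean over CCW-inducer trials
#' (`delta > 0`). Zero-delta trials are ignored; a group left empty by a
#' permutation contributes its overall mean instead (keeping the statistic
#' finite).
#'
#' @param df Data frame with `delta` and `trial_asym`.
#' @return Scalar neural-bias statistic.
#' @export
neural_bias_stat <- function(df) {
  cw <- df$trial_asym[df$delta < 0]
  ccw <- df$trial_asym[df$delta > 0]
  m <- mean(df$trial_asym)
  (if (length(cw)) mean(cw) else m) - (if (length(ccw)) mean(ccw) else m)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> observed = %+.4f, z = %+.3f, p_z = %.4g, p_perm = %.4g (%d iterations, %d subjects)\n",
    x$observed, x$z, x$p_z, x$p_perm, x$n_iter, x$n_subjects))
  invisible(x)
}

#' @rdname signflip_null
#' @param x A `null_distribution` object.
#' @param ... Unused.
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(observed = x$observed, z = x$z, p_z = x$p_z, p_perm = x$p_perm,
         n_iter = x$n_iter, n_subjects = x$n_subjects)
}

#' Plot a permutation null with the observed statistic
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_values),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "null statistic",
                  subtitle = sprintf("z = %+.2f, p = %.4g", object$z, object$p_z))
}
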